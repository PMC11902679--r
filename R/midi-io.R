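#' Note sequence container
#'
#' An in-memory symbolic music clip: one row per note, sorted by onset.
#'
#' @param pitch integer MIDI note numbers in 0--127.
#' @param onset,offset note times in seconds, \code{onset < offset}.
#' @param velocity MIDI velocities in 1--127 (recycled).
#' @param tempo tempo in beats per minute.
#' @return object of class \code{note_sequence}: a data frame with columns
#'   \code{pitch, onset, offset, velocity} and attribute \code{tempo}.
#' @export
note_sequence <- function(pitch = integer(), onset = numeric(),
                          offset = numeric(), velocity = 80L, tempo = 120) {
  n <- length(pitch)
  stopifnot(length(onset) == n, length(offset) == n)
  velocity <- rep_len(as.integer(velocity), n)
  if (n > 0) {
    stopifnot(all(pitch >= 0 & pitch <= 127),
              all(onset < offset),
              all(velocity >= 1 & velocity <= 127))
  }
  ord <- order(onset, pitch)
  df <- data.frame(pitch = as.integer(pitch)[ord], onset = onset[ord],
                   offset = offset[ord], velocity = velocity[ord])
  structure(df, tempo = tempo, class = c("note_sequence", "data.frame"))
}

#' @export
print.note_sequence <- function(x, ...) {
  cat(sprintf("<note_sequence> %d notes, %.2f s, tempo %g BPM\n",
              nrow(x), if (nrow(x)) max(x$offset) else 0, attr(x, "tempo")))
  if (nrow(x)) print.data.frame(utils::head(x, 8))
  invisible(x)
}

# --- Standard MIDI File (format 0) I/O --------------------------------------
# Minimal reader/writer covering note on/off and the set-tempo meta event,
# which is all the pipeline emits and consumes.

.midi_division <- 480L  # ticks per quarter note

.vlq_encode <- function(x) {
  x <- as.integer(x)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0) {
    bytes <- c(x %% 128L, bytes)
    x <- x %/% 128L
  }
  if (length(bytes) > 1)
    bytes[-length(bytes)] <- bytes[-length(bytes)] + 128L
  as.raw(bytes)
}

.int_be <- function(x, width) {
  as.raw(rev((x %/% 256^(0:(width - 1))) %% 256))
}

#' Write a note sequence to a Standard MIDI File
#'
#' Emits a single-track (format 0) file with a set-tempo meta event followed
#' by note on/off pairs on channel 1, at 480 ticks per quarter note.
#'
#' @param notes a \code{\link{note_sequence}}.
#' @param path output file path.
#' @param tempo tempo in BPM; defaults to the sequence's own tempo.
#' @return invisibly, \code{path}.
#' @export
write_midi <- function(notes, path, tempo = NULL) {
  stopifnot(inherits(notes, "note_sequence"))
  tempo <- tempo %||% attr(notes, "tempo") %||% 120
  tick <- function(sec) as.integer(round(sec * .midi_division * tempo / 60))
  ev <- data.frame(tick = integer(), on = logical(), pitch = integer(),
                   vel = integer())
  if (nrow(notes) > 0) {
    ev <- rbind(
      data.frame(tick = tick(notes$onset), on = TRUE, pitch = notes$pitch,
                 vel = notes$velocity),
      data.frame(tick = tick(notes$offset), on = FALSE, pitch = notes$pitch,
                 vel = 0L))
    ev <- ev[order(ev$tick, ev$on), ]  # note-offs first at equal ticks
  }
  body <- c(as.raw(c(0x00, 0xFF, 0x51, 0x03)),      # set tempo
            .int_be(round(60e6 / tempo), 3))
  last <- 0L
  for (i in seq_len(nrow(ev))) {
    body <- c(body, .vlq_encode(ev$tick[i] - last),
              as.raw(c(if (ev$on[i]) 0x90 else 0x80,
                       ev$pitch[i], ev$vel[i])))
    last <- ev$tick[i]
  }
  body <- c(body, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))  # end of track
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), .int_be(6, 4), .int_be(0, 2), .int_be(1, 2),
             .int_be(.midi_division, 2),
             charToRaw("MTrk"), .int_be(length(body), 4), body), con)
  invisible(path)
}

#' Read a Standard MIDI File into a note sequence
#'
#' Parses format 0/1 files: note on/off events (running status supported,
#' note-on with velocity zero treated as note-off) and the first set-tempo
#' meta event; other events are skipped. All tracks are merged.
#'
#' @param path file path.
#' @return a \code{\link{note_sequence}}.
#' @export
read_midi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u <- function(i) as.integer(raw[i])
  be <- function(i, w) sum(u(i:(i + w - 1)) * 256^((w - 1):0))
  if (rawToChar(raw[1:4]) != "MThd") stop("not a Standard MIDI File")
  n_tracks <- be(11, 2)
  division <- be(13, 2)
  pos <- 15
  tempo_bpm <- 120
  notes <- list()
  for (trk in seq_len(n_tracks)) {
    if (rawToChar(raw[pos:(pos + 3)]) != "MTrk") stop("bad track chunk")
    len <- be(pos + 4, 4)
    p <- pos + 8
    end <- p + len
    tick <- 0
    status <- 0L
    active <- list()  # pitch -> (tick, vel)
    while (p < end) {
      # delta time (variable length)
      delta <- 0
      repeat {
        b <- u(p); p <- p + 1
        delta <- delta * 128 + (b %% 128L)
        if (b < 128L) break
      }
      tick <- tick + delta
      b <- u(p)
      if (b >= 128L) { status <- b; p <- p + 1 }
      hi <- status %/% 16L
      if (status == 255L) {           # meta event
        type <- u(p); p <- p + 1
        mlen <- 0
        repeat {
          mb <- u(p); p <- p + 1
          mlen <- mlen * 128 + (mb %% 128L)
          if (mb < 128L) break
        }
        if (type == 81L && mlen == 3) {
          usq <- be(p, 3)
          tempo_bpm <- 60e6 / usq
        }
        p <- p + mlen
      } else if (status %in% 240:247) {  # sysex
        slen <- 0
        repeat {
          sb <- u(p); p <- p + 1
          slen <- slen * 128 + (sb %% 128L)
          if (sb < 128L) break
        }
        p <- p + slen
      } else if (hi %in% c(8L, 9L)) {   # note off / note on
        pitch <- u(p); vel <- u(p + 1); p <- p + 2
        key <- as.character(pitch)
        if (hi == 9L && vel > 0) {
          active[[key]] <- c(tick, vel)
        } else if (!is.null(active[[key]])) {
          notes[[length(notes) + 1]] <- c(pitch, active[[key]][1], tick,
                                          active[[key]][2])
          active[[key]] <- NULL
        }
      } else if (hi %in% c(10L, 11L, 14L)) {
        p <- p + 2                      # two-byte channel messages
      } else if (hi %in% c(12L, 13L)) {
        p <- p + 1                      # one-byte channel messages
      } else {
        stop("unsupported MIDI event, status ", status)
      }
    }
    pos <- end
  }
  sec <- function(t) t * 60 / (division * tempo_bpm)
  if (length(notes) == 0)
    return(note_sequence(tempo = tempo_bpm))
  m <- do.call(rbind, notes)
  note_sequence(pitch = m[, 1], onset = sec(m[, 2]), offset = sec(m[, 3]),
                velocity = m[, 4], tempo = tempo_bpm)
}
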