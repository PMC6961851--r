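#' Ethogram of oromanual/holding phases
#'
#' Ordered phase segments tiling `[first_start, video_length)` as half-open
#' frame intervals. Adjacent segments must alternate between the oromanual
#' and holding phases. The first and last segments are flagged non-interior:
#' their true durations are unknown (the behavior extends beyond the video
#' segment), so duration and switching statistics exclude them.
#'
#' @param start_frame integer vector of 0-based segment start frames, sorted.
#' @param phase character vector, `"oromanual"` or `"holding"` (codes `O`/`H`
#'   accepted).
#' @param video_length_frames total frame count; the last segment ends here.
#' @param grip_left,grip_right optional per-segment grip labels:
#'   `thumb_hold`, `pincer`, `indeterminate`, or `absent`.
#' @return An object of class `ethogram`: a data.frame of segments
#'   (`start`, `end`, `phase`, `grip_left`, `grip_right`, `interior`) with a
#'   `video_length_frames` attribute.
#' @export
ethogram <- function(start_frame, phase, video_length_frames,
                     grip_left = NULL, grip_right = NULL) {
  n <- length(start_frame)
  if (n == 0L) stop_handkin("ethogram needs at least one segment", "handkin_validation_error")
  phase <- normalize_phase(phase)
  if (length(phase) != n) {
    stop_handkin("start_frame and phase differ in length", "handkin_validation_error")
  }
  if (is.unsorted(start_frame, strictly = TRUE)) {
    stop_handkin("segment start frames must be strictly increasing", "handkin_validation_error")
  }
  if (any(start_frame >= video_length_frames) || any(start_frame < 0)) {
    bad <- which(start_frame >= video_length_frames | start_frame < 0)[1L]
    stop_handkin(sprintf("row %d: start_frame %d outside [0, %d)", bad,
                         start_frame[bad], video_length_frames),
                 "handkin_range_error")
  }
  if (n > 1L) {
    same <- phase[-1L] == phase[-n]
    if (any(same)) {
      stop_handkin(sprintf("phases must alternate; row %d repeats '%s'",
                           which(same)[1L] + 1L, phase[which(same)[1L] + 1L]),
                   "handkin_validation_error")
    }
  }
  grips <- c("thumb_hold", "pincer", "indeterminate", "absent")
  gl <- grip_left %||% rep("absent", n)
  gr <- grip_right %||% rep("absent", n)
  gl[is.na(gl) | !nzchar(gl)] <- "absent"
  gr[is.na(gr) | !nzchar(gr)] <- "absent"
  if (!all(gl %in% grips) || !all(gr %in% grips)) {
    stop_handkin("grip labels must be thumb_hold, pincer, indeterminate or absent",
                 "handkin_validation_error")
  }
  seg <- data.frame(start = as.integer(start_frame),
                    end = as.integer(c(start_frame[-1L], video_length_frames)),
                    phase = phase, grip_left = gl, grip_right = gr,
                    interior = c(FALSE, rep(TRUE, max(0L, n - 2L)),
                                 if (n > 1L) FALSE),
                    stringsAsFactors = FALSE)
  structure(seg, class = c("ethogram", "data.frame"),
            video_length_frames = as.integer(video_length_frames))
}

normalize_phase <- function(phase) {
  p <- tolower(as.character(phase))
  p[p == "o"] <- "oromanual"
  p[p == "h"] <- "holding"
  if (!all(p %in% c("oromanual", "holding"))) {
    stop_handkin(sprintf("unknown phase label '%s'",
                         p[!p %in% c("oromanual", "holding")][1L]),
                 "handkin_validation_error")
  }
  p
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d segments over %d frames (%d oromanual, %d holding)\n",
              nrow(x), attr(x, "video_length_frames"),
              sum(x$phase == "oromanual"), sum(x$phase == "holding")))
  NextMethod()
}

#' Read an ethogram annotation file
#'
#' Reads the comma-separated dialect `frame,phase[,grip_left,grip_right]`
#' with a header line and phase codes `O`/`H` (one file per video). Segments
#' are the half-open intervals between consecutive start frames; the last
#' segment ends at the declared video length. Missing grip columns become
#' `"absent"`.
#'
#' @param source path to the annotation file.
#' @param video_length_frames declared video length in frames.
#' @return An [ethogram()].
#' @export
read_ethogram <- function(source, video_length_frames) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("frame", "phase") %in% names(df))) {
    stop_handkin("ethogram file needs 'frame' and 'phase' columns",
                 "handkin_validation_error")
  }
  ethogram(df$frame, df$phase, video_length_frames,
           grip_left = if ("grip_left" %in% names(df)) df$grip_left,
           grip_right = if ("grip_right" %in% names(df)) df$grip_right)
}

#' Write an ethogram annotation file
#'
#' @param eth an [ethogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(eth, path) {
  out <- data.frame(frame = eth$start,
                    phase = ifelse(eth$phase == "oromanual", "O", "H"),
                    grip_left = eth$grip_left, grip_right = eth$grip_right)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frame phase labels from an ethogram
#'
#' @param eth an [ethogram()].
#' @return Character vector of length `video_length_frames`; frames before
#'   the first segment are `NA`.
#' @export
phase_per_frame <- function(eth) {
  nf <- attr(eth, "video_length_frames")
  out <- rep(NA_character_, nf)
  for (i in seq_len(nrow(eth))) {
    out[(eth$start[i] + 1L):eth$end[i]] <- eth$phase[i]
  }
  out
}
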