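## Syllable-level annotations.  An annotation track is a data frame with one
## row per rendered/labelled syllable: onset and offset in seconds, caller
## sex ("m"/"f"), phrase type (pant, bellow, pump, ...), syllable type, and
## an optional sub-phase tag ("cresc"/"decresc") used by the bellow-rate
## comparison.  On disk it is an Audacity label track: three tab-separated
## columns (start, end, label) with 6-decimal seconds and label syntax
## "sex:phrase:syllable[:subphase]".

#' Construct an annotation track
#'
#' @param onset,offset Event times in seconds (`onset < offset`).
#' @param sex `"m"` or `"f"` per event.
#' @param phrase Phrase type per event (e.g. `"pant"`, `"bellow"`).
#' @param syllable Syllable type per event.
#' @param subphase Optional sub-phase tag per event (`NA`, `"cresc"`,
#'   `"decresc"`).
#' @return A data frame of class `annotation_track`, sorted by onset.
#' @export
annotation_track <- function(onset, offset, sex, phrase, syllable,
                             subphase = NA_character_) {
  df <- data.frame(
    onset = as.numeric(onset), offset = as.numeric(offset),
    sex = as.character(sex), phrase = as.character(phrase),
    syllable = as.character(syllable),
    subphase = rep_len(as.character(subphase), length(onset)),
    stringsAsFactors = FALSE
  )
  bad <- which(df$offset <= df$onset)
  if (length(bad)) {
    stop("annotation offset <= onset at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$onset < 0)) stop("negative annotation onsets", call. = FALSE)
  if (!all(df$sex %in% c("m", "f"))) {
    stop('annotation sex must be "m" or "f"', call. = FALSE)
  }
  df <- df[order(df$onset, df$offset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  df
}

.format_label <- function(track) {
  lab <- paste(track$sex, track$phrase, track$syllable, sep = ":")
  has_sub <- !is.na(track$subphase) & nzchar(track$subphase)
  lab[has_sub] <- paste(lab[has_sub], track$subphase[has_sub], sep = ":")
  lab
}

#' Write an annotation track as an Audacity label file
#'
#' @param track An [annotation_track()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  lines <- sprintf("%.6f\t%.6f\t%s", track$onset, track$offset,
                   .format_label(track))
  writeLines(lines, path)
  invisible(path)
}

#' Read an Audacity label file into an annotation track
#'
#' Lines must have at least three tab-separated fields (start, end, label);
#' labels use the `"sex:phrase:syllable[:subphase]"` syntax.  Events are
#' re-sorted by onset; malformed lines are rejected with their line number.
#'
#' @param path Path to a label-track TSV.
#' @return An [annotation_track()].
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty label file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3L)) {
    stop("malformed label line (need 3 tab-separated fields) at line ",
         which(n_fields < 3L)[1L], call. = FALSE)
  }
  onset <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  offset <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(onset) || anyNA(offset)) {
    stop("non-numeric time at line ", which(is.na(onset) | is.na(offset))[1L],
         call. = FALSE)
  }
  bad <- which(offset <= onset)
  if (length(bad)) {
    stop("offset <= onset at line ", bad[1L], call. = FALSE)
  }
  lab <- strsplit(vapply(parts, `[[`, "", 3L), ":", fixed = TRUE)
  nl <- lengths(lab)
  if (any(nl < 3L)) {
    stop('label must be "sex:phrase:syllable" at line ', which(nl < 3L)[1L],
         call. = FALSE)
  }
  annotation_track(
    onset = onset, offset = offset,
    sex = vapply(lab, `[[`, "", 1L),
    phrase = vapply(lab, `[[`, "", 2L),
    syllable = vapply(lab, `[[`, "", 3L),
    subphase = vapply(lab, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, "")
  )
}
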