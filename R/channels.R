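#' Canonical muscle montage
#'
#' Nine bilaterally recorded upper-limb muscles, in the fixed order used for
#' all coefficient vectors: brachioradialis (BR), pronator teres (PT), biceps
#' (B), triceps (T), anterior deltoid (AD), posterior deltoid (PD), pectoralis
#' (PEC), infraspinatus (IS), erector spinae (ES).
#'
#' @format Character vector of muscle abbreviations.
#' @export
emg_muscles <- c("BR", "PT", "B", "T", "AD", "PD", "PEC", "IS", "ES")

#' Body sides, right first (matches the right/left convention of the indexes).
#' @rdname emg_muscles
#' @export
emg_sides <- c("right", "left")

#' Channel labels for the full bilateral montage
#'
#' A channel is identified by the string \code{"<MUSCLE>_<SIDE>"}, e.g.
#' \code{"B_RIGHT"}. The full montage has 18 channels (9 muscles x 2 sides),
#' ordered right side first, muscles in canonical order within each side.
#'
#' @param muscle Muscle abbreviation, one of \code{emg_muscles}.
#' @param side \code{"right"} or \code{"left"}.
#' @return For \code{channel_label}, the canonical (uppercase) label string;
#'   for \code{full_montage}, the 18 canonical labels.
#' @export
channel_label <- function(muscle, side) {
  muscle <- toupper(muscle)
  side <- tolower(side)
  if (!all(muscle %in% emg_muscles))
    stop("unknown muscle abbreviation: ", paste(setdiff(muscle, emg_muscles), collapse = ", "))
  if (!all(side %in% emg_sides))
    stop("side must be 'left' or 'right'")
  paste0(muscle, "_", toupper(side))
}

#' @rdname channel_label
#' @export
full_montage <- function() {
  as.vector(vapply(emg_sides, function(s) channel_label(emg_muscles, s), character(9)))
}

#' Parse a channel label into its muscle and side
#'
#' Case-insensitive; unknown labels yield \code{NA} components.
#'
#' @param label Character vector of channel labels.
#' @return data.frame with columns \code{label} (canonical form), \code{muscle},
#'   \code{side}; \code{NA} where the label is not a montage channel.
#' @export
parse_channel_label <- function(label) {
  up <- toupper(trimws(label))
  m <- regmatches(up, regexec("^([A-Z]+)_(RIGHT|LEFT)$", up))
  muscle <- vapply(m, function(p) if (length(p) == 3L) p[2] else NA_character_, "")
  side <- vapply(m, function(p) if (length(p) == 3L) tolower(p[3]) else NA_character_, "")
  bad <- !is.na(muscle) & !(muscle %in% emg_muscles)
  muscle[bad] <- NA_character_
  side[bad] <- NA_character_
  canonical <- ifelse(is.na(muscle), NA_character_, paste0(muscle, "_", toupper(side)))
  data.frame(label = canonical, muscle = muscle, side = side,
             stringsAsFactors = FALSE)
}
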