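#' Define the eight-stimulus set of a cued statistical-learning experiment
#'
#' The paradigm pairs eight full-colour object images (four animate, four
#' inanimate) one-to-one with eight consonant letter cues. Vowels are reserved
#' for no-go trials and are never paired with a stimulus.
#'
#' @param stimulus_id Character vector of 8 unique stimulus identifiers.
#' @param animacy Character vector of 8 labels, `"animate"` or `"inanimate"`,
#'   exactly four of each.
#' @param category_word One category word per stimulus (used by the semantic
#'   feature model); defaults to `stimulus_id`.
#' @param cue_letter 8 unique consonant cue letters.
#'
#' @return A tibble of class `stimulus_set` with columns `stimulus_id`,
#'   `animacy`, `category_word`, `cue_letter`.
#' @examples
#' stimulus_set()
#' @export
stimulus_set <- function(stimulus_id = c("dog", "tiger", "swan", "elephant",
                                         "car", "hammer", "guitar", "house"),
                         animacy = rep(c("animate", "inanimate"), each = 4),
                         category_word = stimulus_id,
                         cue_letter = c("b", "d", "f", "g", "k", "p", "s", "t")) {
  vowels <- c("a", "e", "i", "o", "u")
  if (length(stimulus_id) != 8L || anyDuplicated(stimulus_id))
    abort("a stimulus set needs exactly 8 unique stimuli")
  animacy <- match.arg(animacy, c("animate", "inanimate"), several.ok = TRUE)
  if (sum(animacy == "animate") != 4L)
    abort("exactly 4 animate and 4 inanimate stimuli are required")
  if (length(cue_letter) != 8L || anyDuplicated(tolower(cue_letter)))
    abort("8 unique cue letters are required")
  if (any(tolower(cue_letter) %in% vowels))
    abort("cue letters must be consonants; vowels mark no-go trials")
  out <- tibble(
    stimulus_id = as.character(stimulus_id),
    animacy = animacy,
    category_word = as.character(category_word),
    cue_letter = tolower(as.character(cue_letter))
  )
  class(out) <- c("stimulus_set", class(out))
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> 8 stimuli (4 animate / 4 inanimate)\n")
  NextMethod()
}

# cue -> expected image lookup (named character vector)
cue_pairing <- function(stimuli) {
  setNames(stimuli$stimulus_id, stimuli$cue_letter)
}
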