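#' Stimulus set: 14 body-part and object images
#'
#' The default set mirrors the experimental design: 4 foot, 4 hand and
#' 4 mouth images plus 2 object images, each presented `repetitions` times
#' (40 by default, 560 presentations in total).
#'
#' @param repetitions presentations per image (default 40).
#' @return a `meg_stimuli` object: `image_id` (1..14), `category` per image,
#'   `repetitions`, and `schedule_length`.
#' @export
stimulus_set <- function(repetitions = 40) {
  if (repetitions < 1) stop_invalid("repetitions must be >= 1")
  category <- rep(c("foot", "hand", "mouth", "object"), times = c(4, 4, 4, 2))
  structure(list(image_id = seq_along(category), category = category,
                 repetitions = as.integer(repetitions),
                 schedule_length = length(category) * as.integer(repetitions)),
            class = "meg_stimuli")
}

#' @export
print.meg_stimuli <- function(x, ...) {
  cat("Stimulus set: ", length(x$image_id), " images (",
      paste(names(table(x$category)), table(x$category), sep = "=",
            collapse = ", "), "), ", x$repetitions,
      " repetitions -> ", x$schedule_length, " presentations\n", sep = "")
  invisible(x)
}

body_categories <- c("foot", "hand", "mouth")
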