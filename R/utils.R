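#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr group_by summarise arrange mutate filter select left_join bind_rows n
#' @importFrom purrr map map_dbl map_int
NULL

# Deterministically derive a child seed from a parent seed and a tag.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_input <- function(msg, class) {
  rlang::abort(msg, class = c(class, "renograph_error"))
}

assert_that <- function(ok, msg, class = "renograph_invalid") {
  if (!isTRUE(ok)) stop_input(msg, class)
  invisible(TRUE)
}

# Flatten an H x W x 3 image array into an n x 3 pixel matrix (column per channel).
pixel_matrix <- function(img) {
  cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
}

# Inverse of pixel_matrix().
matrix_to_image <- function(px, h, w) {
  array(px, dim = c(h, w, 3))
}
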