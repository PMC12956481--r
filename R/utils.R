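## Internal helpers shared across modules.

## Images are numeric arrays H x W x C with values in [0, 1] (C = 3 for RGB).
## Label maps are integer matrices H x W using the coding
## 0 = negative/background, 1 = positive/foreground, 255 = unlabeled.
## All public point coordinates are 0-based (row, col).

LABEL_NEG <- 0L
LABEL_POS <- 1L
LABEL_UNL <- 255L

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  invisible(image)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## quantize [0,1] doubles to the 8-bit grid so PNG round-trips are exact
quantize8 <- function(x) round(clip01(x) * 255) / 255

## deterministic child seeds below 2^31
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

## evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

is_coded_label <- function(x) {
  is.matrix(x) && all(x %in% c(LABEL_NEG, LABEL_POS, LABEL_UNL))
}
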