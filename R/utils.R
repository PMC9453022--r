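#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
## The caller's .Random.seed is restored on exit so generators behave as
## pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-subject (or per-stage) seed from a master seed
#'
#' A small multiplicative hash keeps derived seeds inside the 32-bit integer
#' range so runs reproduce across platforms. Documented so that per-subject
#' streams can be regenerated independently of cohort order.
#'
#' @param master_seed integer master seed.
#' @param index positive integer stream index (e.g. subject number).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(master_seed)) %% m)
  s <- (s * 48271) %% m
  s <- (s + as.numeric(index) * 30269) %% m
  as.integer(s)
}

## Stratified fold assignment: within each class, subjects are shuffled and
## dealt round-robin into k folds.
make_stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (k < 2) stop("need at least 2 folds")
  if (k > min(table(y))) stop("`n_folds` exceeds the smallest class count")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## Column-wise z-standardization with parameters learned on `train` only.
## Zero-variance columns are left centered (scale 1) to avoid NaN.
fit_standardizer <- function(train) {
  mu <- colMeans(train)
  sd_ <- apply(train, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

## %||% as in rlang, for config defaults
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
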