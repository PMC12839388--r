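## Internal helpers shared across modules.

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar is a finite number within bounds
#' @noRd
check_num <- function(x, name, lower = -Inf, upper = Inf,
                      allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  if (!allow_zero && x == 0) stopf("'%s' must be non-zero", name)
  invisible(x)
}

#' Derive a child seed from a master seed, stage name and index.
#'
#' Deterministic integer mixing (no RNG state involved) so that toggling
#' pipeline stages never shifts the random stream of other stages.  All
#' values stay below 2^31 - 1.
#'
#' @param seed master seed (non-negative integer)
#' @param stage character stage label
#' @param index integer counter within the stage
#' @return an integer seed in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, stage, index = 1L) {
  check_num(seed, "seed", lower = 0)
  m <- 2147483647            # 2^31 - 1, prime
  h <- seed %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.numeric(index)) %% m
  as.integer(h %% (m - 1L) + 1)
}

#' Squared euclidean distances from each row of a to each row of b
#' (chunked to bound memory). Returns for each row of a the minimum
#' distance to b and the index attaining it.
#' @noRd
nn_brute <- function(a, b, chunk = 512L) {
  na <- nrow(a)
  if (na == 0L) return(list(dist = numeric(0), index = integer(0)))
  bx <- b[, 1L]; by <- b[, 2L]
  d <- numeric(na); idx <- integer(na)
  for (s in seq(1L, na, by = chunk)) {
    e <- min(s + chunk - 1L, na)
    dx <- outer(a[s:e, 1L], bx, "-")
    dy <- outer(a[s:e, 2L], by, "-")
    d2 <- dx * dx + dy * dy
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    d[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  list(dist = d, index = idx)
}

#' Shoelace area of a polygon given vertex coordinates (closed implicitly).
#' @noRd
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' MD5 of a canonical JSON rendering of a list (config provenance hash).
#' @noRd
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}
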