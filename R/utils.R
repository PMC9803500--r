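`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' disturb the caller's random stream. A `NULL` seed evaluates the
#' expression as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a named sub-stream seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed plus a stage
#' name, so stages can be re-run in isolation and still reproduce a full
#' run. The derivation is a small multiplicative hash kept below 2^31.
#'
#' @param seed integer root seed.
#' @param stream character stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "phantom") != derive_seed(1, "cohort")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647  # 2^31 - 1, prime
  h <- (abs(seed) %% m)
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Otsu threshold of a numeric array via EBImage on a [0, 1] rescaled copy.
otsu_threshold <- function(x, levels = 256L) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) stop("cannot threshold a constant volume", call. = FALSE)
  scaled <- (x - r[1]) / (r[2] - r[1])
  # one global threshold: EBImage computes per-frame thresholds on 3D
  # images, so flatten to a single frame first
  scaled <- matrix(as.vector(scaled), nrow = 1)
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = levels)
  r[1] + t01 * (r[2] - r[1])
}

# MD5 of an R object via its canonical JSON serialisation.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

stop_user <- function(...) {
  cnd <- simpleError(paste0(...))
  class(cnd) <- c("vrsquant_user_error", class(cnd))
  stop(cnd)
}
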