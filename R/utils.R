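# internal helpers shared across modules

# Evaluate `code` with the RNG temporarily seeded; the caller's RNG state is
# restored afterwards. seed = NULL means "use the current RNG stream".
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# row-wise sd of a matrix, denominator n - 1; rows with n < 2 give NA
.row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- (rowSums(x * x) - n * m * m) / (n - 1)
  sqrt(pmax(v, 0))
}
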