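#' @importFrom methods new validObject is slot
#' @importFrom stats rbinom rmultinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")
AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the random number generator seeded to \code{seed} and
#' restores the caller's RNG state afterwards, so package functions never leak
#' or consume global random state.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stable 31-adic string hash below 2^31, used to fan the pipeline seed out to
# per-sample child seeds without platform dependence
stableHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 17
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147480017
  as.integer(h)
}

childSeed <- function(seed, sample_id) {
  as.integer((as.numeric(seed) * 1000003 + stableHash(sample_id)) %% 2147483629)
}

# 3 significant figures, the reporting convention used throughout
signif3 <- function(x) signif(x, 3)

# byte-wise (C-locale) ordering so top-N tie-breaks are platform stable
orderDesc <- function(value, tie) order(-value, tie, method = "radix")

isDna <- function(x) !grepl("[^ACGT]", x)

randomDna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}
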