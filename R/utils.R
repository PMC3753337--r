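#' @importFrom rlang %||% .data abort
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join n row_number distinct count pull rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad rnorm runif rbinom pchisq p.adjust setNames
#'   quantile sd var
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched. All stochastic operations in the package
# take explicit seeds and go through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (keeps every seed
# below .Machine$integer.max).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

random_dna <- function(n, base_freq = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_freq), collapse = "")
}

# A base different from every base in `avoid` (used to pin planted junction
# boundaries so microhomology cannot extend by chance).
other_base <- function(avoid) {
  cand <- setdiff(DNA_BASES, unique(avoid))
  cand[1L]
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}
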