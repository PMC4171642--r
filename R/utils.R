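# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a component
# name, so toggling one random component never shifts the draws of another.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Run code under set.seed(derived) without disturbing the caller's RNG state.
with_substream <- function(seed, name, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(substream_seed(seed, name))
  force(code)
}

# Expression tables travel as tibbles with a `sample_id` column followed by
# one numeric column per gene; these two convert to/from the matrix form the
# numerical code wants.
expr_to_matrix <- function(expression) {
  stopifnot(is.data.frame(expression), "sample_id" %in% names(expression))
  m <- as.matrix(expression[setdiff(names(expression), "sample_id")])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- as.character(expression$sample_id)
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m)
  out <- tibble(sample_id = rownames(m)) %>% dplyr::bind_cols(out)
  out
}

expr_genes <- function(expression) setdiff(names(expression), "sample_id")

check_binary <- function(x, what) {
  if (!all(x %in% c(0L, 1L, NA))) {
    abort(paste0("`", what, "` must be binary 0/1"))
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
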