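#' Population model for unidimensional binary data
#'
#' Describes the data-generating population: `p` congeneric items measuring a
#' single latent attribute with a common standardized loading, dichotomized
#' at a common marginal split.  The implied population correlation matrix is
#' compound symmetric with `loading^2` off the diagonal, i.e. the structure
#' of a one-factor model in which the latent variable contributes equally to
#' every item.
#'
#' @param p number of items.
#' @param loading standardized loading of every item on the latent
#'   attribute, in (0, 1).
#' @param split_prob marginal probability of code 1 after dichotomization.
#' @param n sample size (rows per generated data set).
#' @return an object of class `mdcfa_population`.
#' @examples
#' pm <- population_model(p = 20, loading = 0.35, n = 500)
#' population_correlation(pm)[1:3, 1:3]
#' @export
population_model <- function(p = 20, loading = 0.35, split_prob = 0.5,
                             n = 500) {
  stopifnot(p >= 1, n >= 2)
  if (!(loading >= 0 && loading < 1))
    stop("invalid population model: 'loading' must be in [0, 1)")
  if (!(split_prob > 0 && split_prob < 1))
    stop("'split_prob' must be in (0, 1)")
  structure(list(p = as.integer(p), loading = loading,
                 split_prob = split_prob, n = as.integer(n)),
            class = "mdcfa_population")
}

#' @export
print.mdcfa_population <- function(x, ...) {
  cat(sprintf(
    "Population model: %d items, loading %.3f, split P(1) = %.2f, n = %d\n",
    x$p, x$loading, x$split_prob, x$n))
  invisible(x)
}

#' Population correlation matrix implied by a population model
#'
#' Unit diagonal and `loading^2` everywhere off the diagonal (the relational
#' pattern of a one-factor model with equal loadings).
#'
#' @param model an [population_model()] object.
#' @return a `p x p` positive-definite correlation matrix.
#' @export
population_correlation <- function(model) {
  stopifnot(inherits(model, "mdcfa_population"))
  p <- model$p
  r <- model$loading^2
  R <- matrix(r, p, p)
  diag(R) <- 1
  R
}

#' Simulate continuous multivariate-normal data
#'
#' Draws `n` iid rows from N(0, R) where R is the population correlation
#' matrix, via its Cholesky factor.
#'
#' @param model an [population_model()] object.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return an `n x p` numeric matrix.
#' @export
simulate_continuous <- function(model, seed) {
  R <- population_correlation(model)
  L <- tryCatch(chol(R), error = function(e)
    stop("population correlation matrix is not positive definite"))
  set.seed(seed)
  Z <- matrix(rnorm(model$n * model$p), model$n, model$p)
  Z %*% L
}

#' Dichotomize continuous data into a binary dataset
#'
#' An entry is coded 1 when the continuous value exceeds the standard-normal
#' quantile `qnorm(1 - split_prob)`, so the marginal probability of a 1 is
#' approximately `split_prob` (exactly 0.5 splits at zero).
#'
#' @param x continuous numeric matrix.
#' @param split_prob target marginal probability of code 1, in (0, 1).
#' @param provenance optional list recording generation seed / model.
#' @return a [binary_dataset()] with values in \{0, 1\}.
#' @export
dichotomize <- function(x, split_prob = 0.5, provenance = NULL) {
  stopifnot(is.matrix(x), split_prob > 0, split_prob < 1)
  cut <- qnorm(1 - split_prob)
  v <- matrix(as.integer(x > cut), nrow(x), ncol(x))
  colnames(v) <- sprintf("item%02d", seq_len(ncol(v)))
  binary_dataset(v, design = NULL, provenance = provenance)
}

#' Binary dataset container
#'
#' An `n x p` matrix over \{0, 1, NA\} (NA encodes a missing response)
#' together with the missingness design that produced the NAs and a
#' provenance record.
#'
#' @param values integer matrix over 0/1/NA.
#' @param design an optional [missing_design()].
#' @param provenance optional list (seed, population model, ...).
#' @return an object of class `mdcfa_binary`.
#' @export
binary_dataset <- function(values, design = NULL, provenance = NULL) {
  stopifnot(is.matrix(values))
  ok <- values %in% c(0L, 1L) | is.na(values)
  if (!all(ok)) stop("binary dataset entries must be 0, 1 or NA")
  storage.mode(values) <- "integer"
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("item%02d", seq_len(ncol(values)))
  structure(list(values = values, design = design, provenance = provenance),
            class = "mdcfa_binary")
}

#' @export
print.mdcfa_binary <- function(x, ...) {
  v <- x$values
  cat(sprintf("Binary dataset: %d x %d, %d missing entries\n",
              nrow(v), ncol(v), sum(is.na(v))))
  if (!is.null(x$design))
    cat(sprintf("  design: %.0f%% per column in columns %s (%s scheme)\n",
                100 * x$design$rate,
                paste(range(x$design$missing_columns), collapse = "-"),
                x$design$scheme))
  invisible(x)
}

#' Planned-missingness design
#'
#' Fixed columns, a per-column deletion rate and a row-selection scheme.
#' Under the default `"shared"` scheme one uniformly sampled set of
#' `round(rate * n)` respondents is missing on *all* design columns, the
#' block structure of a planned missing data design in which a subset of
#' participants skips a whole block of items.  Under `"independent"` the
#' rows are drawn anew for each design column.
#'
#' @param missing_columns 1-based column indices that carry missing data.
#' @param rate fraction of entries removed per design column, in [0, 1).
#' @param scheme row-selection rule, `"shared"` or `"independent"`.
#' @param seed integer seed for the row draws.
#' @return an object of class `mdcfa_design`.
#' @export
missing_design <- function(missing_columns, rate,
                           scheme = c("shared", "independent"), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(rate >= 0, rate < 1, all(missing_columns >= 1))
  structure(list(missing_columns = as.integer(sort(missing_columns)),
                 rate = rate, scheme = scheme, seed = as.integer(seed)),
            class = "mdcfa_design")
}

#' Inject planned missingness into a complete binary dataset
#'
#' Sets exactly `round(rate * n)` entries per design column to NA according
#' to the design's row-selection scheme; all other columns are untouched.
#'
#' @param data a complete [binary_dataset()].
#' @param design a [missing_design()].
#' @return a [binary_dataset()] with NAs in the design columns.
#' @export
inject_missing <- function(data, design) {
  stopifnot(inherits(data, "mdcfa_binary"), inherits(design, "mdcfa_design"))
  v <- data$values
  if (anyNA(v)) stop("input data must be complete")
  n <- nrow(v)
  if (max(design$missing_columns) > ncol(v))
    stop("design columns exceed data columns")
  k <- round(design$rate * n)
  if (design$rate > 0 && k < 1) {
    warning("rate * n < 1: no entries removed")
    k <- 0
  }
  if (k > 0) {
    set.seed(design$seed)
    if (design$scheme == "shared") {
      rows <- sample.int(n, k)
      v[rows, design$missing_columns] <- NA_integer_
    } else {
      for (j in design$missing_columns) {
        v[sample.int(n, k), j] <- NA_integer_
      }
    }
  }
  binary_dataset(v, design = design, provenance = data$provenance)
}

#' Generate a binary dataset in one call
#'
#' Convenience pipeline: simulate continuous data, dichotomize, and (when a
#' design with a positive rate is given) inject planned missingness.  Row
#' draws for the missingness use a seed derived from `seed` so the complete
#' data underlying different designs are identical for identical seeds.
#'
#' @param model a [population_model()].
#' @param seed integer seed.
#' @param design optional [missing_design()]; its `seed` field is replaced
#'   by one derived from `seed`.
#' @return a [binary_dataset()].
#' @export
generate_binary <- function(model, seed, design = NULL) {
  x <- simulate_continuous(model, seed)
  b <- dichotomize(x, model$split_prob,
                  provenance = list(seed = seed, model = model))
  if (!is.null(design) && design$rate > 0) {
    design$seed <- derive_seed(seed, 7L)
    b <- inject_missing(b, design)
  }
  b
}

#' Write / read a binary dataset as CSV
#'
#' Header row `item01..itemNN`; missing entries written as the sentinel
#' (default `"NA"`, empty string also accepted on reading).
#'
#' @param data a [binary_dataset()].
#' @param path file path.
#' @param na sentinel string for missing entries.
#' @return `read_binary_csv` returns a [binary_dataset()].
#' @export
write_binary_csv <- function(data, path, na = "NA") {
  stopifnot(inherits(data, "mdcfa_binary"))
  write.csv(as.data.frame(data$values), path, row.names = FALSE, na = na)
  invisible(path)
}

#' @rdname write_binary_csv
#' @export
read_binary_csv <- function(path, na = c("NA", "")) {
  df <- read.csv(path, na.strings = na, check.names = FALSE)
  binary_dataset(as.matrix(df))
}

#' Read a generation config from YAML
#'
#' Fields: `n`, `p`, `loading`, `split_prob`, `missing_columns`, `rate`,
#' `scheme`, `seed`.  Missing fields fall back to the study defaults
#' (500 x 20, loading 0.35, median split).
#'
#' @param path YAML file path.
#' @return a list with elements `model` ([population_model()]), `design`
#'   ([missing_design()] or NULL) and `seed`.
#' @export
read_datagen_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  model <- population_model(p = cfg$p %||% 20, loading = cfg$loading %||% 0.35,
                            split_prob = cfg$split_prob %||% 0.5,
                            n = cfg$n %||% 500)
  design <- NULL
  if (!is.null(cfg$missing_columns) && (cfg$rate %||% 0) > 0)
    design <- missing_design(cfg$missing_columns, cfg$rate,
                             scheme = cfg$scheme %||% "shared",
                             seed = cfg$seed %||% 1L)
  list(model = model, design = design, seed = cfg$seed %||% 1L)
}
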