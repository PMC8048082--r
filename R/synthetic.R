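#' Specify a synthetic mt-QSAR dataset
#'
#' The synthetic generator emulates the structure of the case-study datasets
#' this package is designed for: several categorical condition columns with
#' stated element cardinalities, a class-imbalanced `+1`/`-1` response, and
#' per-(element, descriptor) mean shifts that make the Box-Jenkins deviation
#' descriptors (and nothing else) carry the class signal. The defaults are
#' shaped like a medium kinase-inhibitor panel: 726 data points, a 3-column
#' condition ontology of cardinalities 4 x 8 x 2, and a 74% active fraction.
#'
#' @param n_rows number of data points (>= 2).
#' @param n_descriptors number of input descriptors. The first
#'   `ceiling(n_descriptors / 2)` are informative (class-shifted); the rest
#'   are pure noise.
#' @param condition_cardinalities integer vector, one entry per condition
#'   column, giving the number of distinct elements in that column (>= 1).
#' @param active_fraction proportion of `+1` rows, in (0, 1).
#' @param effect_size magnitude of the mean shift separating inactive rows
#'   from the active element mean, in descriptor units. `0` produces a
#'   dataset with no class signal at all.
#' @param noise_sd standard deviation of the Gaussian descriptor noise.
#' @param seed integer seed; identical specs yield byte-identical datasets.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 726, n_descriptors = 10,
                           condition_cardinalities = c(4, 8, 2),
                           active_fraction = 0.74, effect_size = 1,
                           noise_sd = 0.5, seed = 1) {
  if (n_rows < 2) stop("n_rows must be >= 2", call. = FALSE)
  if (n_descriptors < 1) stop("n_descriptors must be >= 1", call. = FALSE)
  if (length(condition_cardinalities) < 1 || any(condition_cardinalities < 1)) {
    stop("every condition column needs cardinality >= 1", call. = FALSE)
  }
  if (active_fraction <= 0 || active_fraction >= 1) {
    stop("active_fraction must lie strictly inside (0,1)", call. = FALSE)
  }
  if (effect_size < 0 || noise_sd < 0) stop("effect_size and noise_sd must be >= 0", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows),
                 n_descriptors = as.integer(n_descriptors),
                 condition_cardinalities = as.integer(condition_cardinalities),
                 active_fraction = active_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic mt-QSAR dataset
#'
#' Sampling model: each condition column element is drawn uniformly; each
#' (condition column, element, descriptor) pair gets a latent baseline mean
#' ~ N(0, 1) shared by both classes, so element means genuinely differ and
#' deviation descriptors are required to recover the signal. Informative
#' descriptors of inactive rows are additionally shifted by `-effect_size`
#' relative to the active element mean. Labels are redrawn (seeded,
#' deterministic) until the realised active fraction is within 3 binomial
#' standard errors of the requested one.
#'
#' @param spec a [synthetic_spec()].
#' @param with_p_user if `TRUE`, attach a `p_user` column holding, per row,
#'   the product over condition columns of that element's frequency in the
#'   generated table (an a-priori probability factor in the style used by
#'   the Method 4 operator).
#' @param tag_validation_fraction if non-`NULL`, also attach a pre-defined
#'   `set_tag` column assigning about this fraction of rows to `"Test"`.
#' @return an [mtqsar_dataset()] with attributes `informative` (names of the
#'   planted informative descriptors) and `spec`.
#' @examples
#' ds <- generate_synthetic(synthetic_spec(n_rows = 50, seed = 7))
#' attr(ds, "informative")
#' @export
generate_synthetic <- function(spec, with_p_user = FALSE,
                               tag_validation_fraction = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_rows
  D <- spec$n_descriptors
  cards <- spec$condition_cardinalities
  C <- length(cards)

  # labels: retry until realised fraction within 3 SE of the target
  se3 <- 3 * sqrt(spec$active_fraction * (1 - spec$active_fraction) / n)
  for (attempt in 1:100) {
    y <- ifelse(stats::runif(n) < spec$active_fraction, 1L, -1L)
    if (abs(mean(y == 1L) - spec$active_fraction) <= se3 &&
        length(unique(y)) == 2L) break
  }

  cond <- as.data.frame(lapply(seq_len(C), function(j) {
    paste0("c", j, "e", sample.int(cards[j], n, replace = TRUE))
  }))
  names(cond) <- paste0("cond", seq_len(C))

  n_inf <- ceiling(D / 2)
  desc_names <- paste0("X", seq_len(D))

  # latent per-(column, element, descriptor) baselines
  mu <- lapply(seq_len(C), function(j) {
    m <- matrix(stats::rnorm(cards[j] * D), nrow = cards[j], ncol = D)
    rownames(m) <- paste0("c", j, "e", seq_len(cards[j]))
    m
  })

  X <- matrix(0, nrow = n, ncol = D, dimnames = list(NULL, desc_names))
  for (j in seq_len(C)) X <- X + mu[[j]][cond[[j]], , drop = FALSE] / C
  shift <- matrix(0, n, D)
  shift[y == -1L, seq_len(n_inf)] <- -spec$effect_size
  X <- X + shift + matrix(stats::rnorm(n * D, sd = spec$noise_sd), n, D)

  p_user <- NULL
  if (with_p_user) {
    p_user <- rep(1, n)
    for (j in seq_len(C)) {
      freq <- table(cond[[j]]) / n
      p_user <- p_user * as.numeric(freq[cond[[j]]])
    }
  }
  set_tag <- NULL
  if (!is.null(tag_validation_fraction)) {
    stopifnot(tag_validation_fraction > 0, tag_validation_fraction < 1)
    set_tag <- ifelse(stats::runif(n) < tag_validation_fraction, "Test", "Train")
  }

  ds <- mtqsar_dataset(ids = sprintf("case%04d", seq_len(n)), response = y,
                       conditions = cond, descriptors = X,
                       set_tag = set_tag, p_user = p_user)
  attr(ds, "informative") <- desc_names[seq_len(n_inf)]
  attr(ds, "spec") <- spec
  ds
}
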