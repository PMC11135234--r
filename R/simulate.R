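#' The 96 trinucleotide-context mutation types
#'
#' Single-base substitutions are conventionally collapsed to the six
#' pyrimidine-referenced subtypes (C>A, C>G, C>T, T>A, T>C, T>G) and expanded
#' by the immediate 5' and 3' flanking bases, giving 6 x 4 x 4 = 96 mutation
#' types. Labels follow the standard `5'[ref>alt]3'` notation and are ordered
#' subtype-major, then 5' base, then 3' base, both alphabetical — so the
#' first label is `A[C>A]A`.
#'
#' @return character vector of 96 unique labels.
#' @export
mutation_types <- function() {
  subtypes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  labels <- character(0)
  for (s in subtypes)
    for (p5 in bases)
      for (p3 in bases)
        labels <- c(labels, paste0(p5, "[", s, "]", p3))
  labels
}

#' Simulate distinct mutational signatures
#'
#' Each signature is a probability distribution over the `K` mutation types,
#' drawn as a symmetric Dirichlet with the given concentration (small values
#' give sparse, peaked signatures, like real mutational processes). A
#' distinctness guard resamples any signature whose cosine similarity to an
#' earlier one reaches `max_cosine`, preventing an accidentally
#' rank-deficient ground truth.
#'
#' @param P number of signatures (processes).
#' @param K number of mutation types, `K >= P`.
#' @param concentration Dirichlet concentration, `> 0`.
#' @param seed integer seed.
#' @param max_cosine pairwise cosine-similarity ceiling.
#' @return K x P matrix; every column sums to 1.
#' @export
simulate_signatures <- function(P, K = 96L, concentration = 0.1, seed = 1L,
                                max_cosine = 0.9) {
  if (P < 1L) stop("P must be >= 1", call. = FALSE)
  if (K < P) stop("K must be >= P", call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rdirichlet1 <- function() {
    g <- stats::rgamma(K, shape = concentration)
    if (sum(g) == 0) g[sample.int(K, 1L)] <- 1   # guard against underflow
    g / sum(g)
  }
  S <- matrix(0, K, P)
  for (p in seq_len(P)) {
    for (attempt in 1:100) {
      cand <- rdirichlet1()
      ok <- p == 1L || all(apply(S[, seq_len(p - 1L), drop = FALSE], 2L,
        function(s) sum(s * cand) / sqrt(sum(s^2) * sum(cand^2))) < max_cosine)
      if (ok) { S[, p] <- cand; break }
      if (attempt == 100L)
        stop("could not draw ", P, " signatures with pairwise cosine < ",
             max_cosine, "; lower the concentration", call. = FALSE)
    }
  }
  S
}

#' Simulate a mutational-process catalog with known rank
#'
#' Emulates the standard benchmark construction for signature extraction:
#' `n_processes` ground-truth signatures over the 96 trinucleotide-context
#' mutation types, per-genome exposures drawn log-uniformly over
#' `[0.05, 1] * exposure_scale`, expected catalog
#' \eqn{\Lambda = signatures \times exposures}, and observed counts drawn
#' entrywise Poisson(\eqn{\Lambda}) (or \eqn{\Lambda} rounded when
#' `poisson_noise = FALSE`). The catalog is mutation types x genomes, the
#' orientation in which signature NMF factors mutation types.
#'
#' @param n_processes ground-truth rank (number of mutational processes).
#' @param n_genomes number of simulated genomes (samples).
#' @param mutation_alphabet row labels; defaults to the 96 standard types.
#' @param signature_concentration Dirichlet concentration of the signatures.
#' @param exposure_scale upper bound of the per-process exposure draw, in
#'   expected mutations per genome contributed by one process at full
#'   intensity.
#' @param poisson_noise add Poisson counting noise (the benchmark default).
#' @param seed integer seed.
#' @return object of class `synthetic_catalog`: `counts` (K x G matrix),
#'   `true_signatures` (K x P), `true_exposures` (P x G), `lambda` (expected
#'   counts), and the generating `spec`.
#' @examples
#' cat10 <- simulate_catalog(seed = 1)
#' dim(cat10$counts)   # 96 x 100
#' @export
simulate_catalog <- function(n_processes = 10L, n_genomes = 100L,
                             mutation_alphabet = mutation_types(),
                             signature_concentration = 0.1,
                             exposure_scale = 1000, poisson_noise = TRUE,
                             seed = 1L) {
  K <- length(mutation_alphabet)
  if (anyDuplicated(mutation_alphabet))
    stop("mutation_alphabet labels must be unique", call. = FALSE)
  if (exposure_scale <= 0) stop("exposure_scale must be positive", call. = FALSE)
  sig <- simulate_signatures(n_processes, K, signature_concentration,
                             seed = derive_seed(seed, 1L, 0L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, 2L, 0L))
  # log-uniform exposures: every process is active in every genome but with
  # intensities spread over ~1.3 orders of magnitude
  E <- matrix(exp(stats::runif(n_processes * n_genomes,
                               log(0.05 * exposure_scale),
                               log(exposure_scale))),
              n_processes, n_genomes)
  lambda <- sig %*% E
  counts <- if (poisson_noise) {
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  } else round(lambda)
  genomes <- paste0("genome", seq_len(n_genomes))
  procs <- paste0("process", seq_len(n_processes))
  dimnames(counts) <- list(mutation_alphabet, genomes)
  dimnames(lambda) <- list(mutation_alphabet, genomes)
  dimnames(sig) <- list(mutation_alphabet, procs)
  dimnames(E) <- list(procs, genomes)
  structure(list(
    counts = counts, true_signatures = sig, true_exposures = E,
    lambda = lambda,
    spec = list(n_processes = as.integer(n_processes),
                n_genomes = as.integer(n_genomes),
                signature_concentration = signature_concentration,
                exposure_scale = exposure_scale,
                poisson_noise = poisson_noise, seed = as.integer(seed))),
    class = "synthetic_catalog")
}

#' @export
#' @method print synthetic_catalog
print.synthetic_catalog <- function(x, ...) {
  cat("Synthetic mutational catalog: ", nrow(x$counts), " mutation types x ",
      ncol(x$counts), " genomes, ", x$spec$n_processes,
      " ground-truth processes",
      if (x$spec$poisson_noise) ", Poisson noise" else "", "\n", sep = "")
  invisible(x)
}

#' Generic low-rank nonnegative test fixture
#'
#' A positive rank-`r` product `A B` (entries uniform on (0, 1]) with
#' optional additive Gaussian noise truncated at zero, used throughout the
#' test-suite where a matrix of known rank is needed.
#'
#' @param m,n dimensions.
#' @param r exact rank of the noiseless product.
#' @param noise_sd standard deviation of the additive noise; 0 for an exact
#'   rank-`r` matrix.
#' @param seed integer seed.
#' @return m x n labeled nonnegative matrix.
#' @export
lowrank_matrix <- function(m, n, r, noise_sd = 0, seed = 1L) {
  r <- check_rank(r, m, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  A <- matrix(1 - stats::runif(m * r), m, r)
  B <- matrix(1 - stats::runif(r * n), r, n)
  V <- A %*% B
  if (noise_sd > 0)
    V <- pmax(V + matrix(stats::rnorm(m * n, sd = noise_sd), m, n), 0)
  dimnames(V) <- list(paste0("f", seq_len(m)), paste0("s", seq_len(n)))
  V
}
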