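#' Trajectory parameters for a balanced allele
#'
#' Bundles the three parameters of the heterozygote-advantage model: the
#' scaled selection coefficient `S = 4 * Ne * s2` (where `s2` is the fitness
#' advantage of the heterozygote over the ancestral homozygote), the
#' deterministic equilibrium frequency `f_eq` of the derived allele, and the
#' allele age `T_age` in coalescent units of `4 * Ne` generations.
#'
#' @param S scaled heterozygote selection coefficient, `> 0`.
#' @param f_eq equilibrium derived-allele frequency, strictly in (0, 1).
#' @param T_age allele age in coalescent units (`1` unit = `4 Ne`
#'   generations), `>= 0`.
#' @return An object of class `"trajectory_params"`.
#' @examples
#' trajectory_params(S = 500, f_eq = 0.45, T_age = 2.21)
#' @export
trajectory_params <- function(S, f_eq, T_age) {
  if (!is.numeric(S) || length(S) != 1L || S <= 0)
    stop("`S` must be a single positive number", call. = FALSE)
  if (!is.numeric(f_eq) || length(f_eq) != 1L || f_eq <= 0 || f_eq >= 1)
    stop("`f_eq` must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(T_age) || length(T_age) != 1L || T_age < 0)
    stop("`T_age` must be >= 0", call. = FALSE)
  structure(list(S = S, f_eq = f_eq, T_age = T_age),
            class = "trajectory_params")
}

#' Genotype fitnesses implied by (S, f_eq) at a rescaled population size
#'
#' With the heterozygote as the fitness reference (`w_het = 1`), the
#' ancestral homozygote is penalised by `s2 = S / (4 * N_sim)` and the
#' derived homozygote by `s1 = s2 * (1 - f_eq) / f_eq`, so that the
#' deterministic equilibrium `s2 / (s1 + s2)` equals `f_eq`.
#'
#' @param S scaled heterozygote selection coefficient.
#' @param f_eq equilibrium derived-allele frequency in (0, 1).
#' @param N_sim rescaled diploid population size used for simulation.
#' @return An object of class `"genotype_fitnesses"`: a list with
#'   `w_anc_hom`, `w_het`, `w_der_hom`.
#' @examples
#' w <- fitnesses_from_params(S = 500, f_eq = 0.45, N_sim = 10000)
#' equilibrium_frequency(w)  # 0.45
#' @export
fitnesses_from_params <- function(S, f_eq, N_sim) {
  p <- trajectory_params(S, f_eq, T_age = 0)  # reuse validation of S, f_eq
  s2 <- p$S / (4 * N_sim)
  s1 <- s2 * (1 - p$f_eq) / p$f_eq
  if (s1 >= 1 || s2 >= 1)
    stop("selection too strong at this `N_sim` (a homozygote fitness would ",
         "be <= 0); increase `N_sim`", call. = FALSE)
  structure(list(w_anc_hom = 1 - s2, w_het = 1, w_der_hom = 1 - s1),
            class = "genotype_fitnesses")
}

#' Deterministic equilibrium frequency of an overdominant polymorphism
#'
#' @param fitnesses a `"genotype_fitnesses"` object or a numeric vector
#'   `c(w_anc_hom, w_het, w_der_hom)` with the heterozygote fittest.
#' @return The equilibrium derived-allele frequency `s2 / (s1 + s2)`, where
#'   `s1 = (w_het - w_der_hom) / w_het` and `s2 = (w_het - w_anc_hom) / w_het`.
#' @examples
#' equilibrium_frequency(c(0.98, 1, 0.99))  # 2/3
#' @export
equilibrium_frequency <- function(fitnesses) {
  w <- unlist(fitnesses, use.names = FALSE)
  if (length(w) != 3L || !is.numeric(w))
    stop("`fitnesses` must supply three genotype fitnesses", call. = FALSE)
  w_anc <- w[1]; w_het <- w[2]; w_der <- w[3]
  if (w_het <= max(w_anc, w_der))
    stop("fitnesses are not overdominant: the heterozygote must be strictly ",
         "fittest", call. = FALSE)
  s1 <- (w_het - w_der) / w_het
  s2 <- (w_het - w_anc) / w_het
  s2 / (s1 + s2)
}

#' Simulate a derived-allele frequency trajectory under heterozygote advantage
#'
#' Forward Wright-Fisher simulation from a single copy at the allele's origin
#' to the present: each generation applies the deterministic selection update
#' followed by binomial resampling of `2 * N_sim` allele copies. The path
#' runs for `round(T_age * 4 * N_sim)` generations; attempts on which the
#' allele is lost or fixed before the present are rejected and resimulated.
#'
#' @param params a [trajectory_params()] object.
#' @param N_sim rescaled diploid population size (default 5000; selection and
#'   mutation are rescaled through it, so downstream statistics are invariant
#'   to its value up to Monte-Carlo error).
#' @param max_rejects maximum number of absorbed attempts before giving up.
#' @param seed optional integer seed (op-local stream).
#' @return An object of class `"trajectory"`: list with `freqs` (derived
#'   frequency per past generation, element 1 = present, last element =
#'   origin at `1 / (2 N_sim)`), `N_sim`, `params` and the rejection count.
#' @examples
#' tr <- simulate_trajectory(trajectory_params(1000, 0.5, 0.1),
#'                           N_sim = 1000, seed = 1)
#' tr$freqs[length(tr$freqs)] == 1 / 2000
#' @export
simulate_trajectory <- function(params, N_sim = 5000, max_rejects = 1000,
                                seed = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  if (N_sim < 100) stop("`N_sim` must be >= 100", call. = FALSE)
  if (max_rejects < 1) stop("`max_rejects` must be >= 1", call. = FALSE)
  fitnesses_from_params(params$S, params$f_eq, N_sim)  # feasibility check
  s2 <- params$S / (4 * N_sim)
  s1 <- s2 * (1 - params$f_eq) / params$f_eq
  n_gen <- round(params$T_age * 4 * N_sim)
  set_op_seed(seed, "simulate_trajectory")
  res <- .wf_trajectory_cpp(s1, s2, as.integer(n_gen), as.integer(N_sim),
                            as.integer(max_rejects))
  if (is.null(res$freqs))
    stop(sprintf(paste0("trajectory rejected %d times without surviving to ",
                        "the present (near-neutral, loss-dominated regime); ",
                        "increase `max_rejects` or `S`"), res$rejects),
         call. = FALSE)
  structure(list(freqs = rev(res$freqs),  # present first
                 N_sim = N_sim, params = params, rejects = res$rejects),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(paste0("Allele-frequency trajectory: %d generations, ",
                     "N_sim = %d\n  present freq %.4f, origin freq %.2g, ",
                     "%d rejected attempt(s)\n"),
              length(x$freqs) - 1L, x$N_sim, x$freqs[1],
              x$freqs[length(x$freqs)], x$rejects))
  invisible(x)
}

#' Write / read a trajectory as two-column TSV
#'
#' Columns are `generation_before_present` (0 = present) and `frequency`,
#' written with full double precision so the round trip is exact.
#'
#' @param trajectory a `"trajectory"` object.
#' @param file path to write to / read from.
#' @rdname trajectory_io
#' @export
write_trajectory_tsv <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(
    generation_before_present = seq_along(trajectory$freqs) - 1L,
    frequency = sprintf("%.17g", trajectory$freqs))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @param N_sim,params metadata to attach on read (the TSV stores only the
#'   path itself).
#' @rdname trajectory_io
#' @export
read_trajectory_tsv <- function(file, N_sim = NULL, params = NULL) {
  df <- read.table(file, header = TRUE, sep = "\t")
  freqs <- as.numeric(df$frequency)
  N <- N_sim %||% round(1 / (2 * freqs[length(freqs)]))
  structure(list(freqs = freqs, N_sim = N, params = params, rejects = NA),
            class = "trajectory")
}
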