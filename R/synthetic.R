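#' Parametric cfDNA fragment-length source profile
#'
#' Builds a probability distribution over fragment length as a mixture of
#' (i) a Gaussian mono-nucleosome mode, (ii) a Gaussian di-nucleosome mode one
#' nucleosome-repeat further right, and (iii) a comb of narrow Gaussian bumps
#' every `periodicity` bp below the main mode with geometrically decaying
#' amplitude — the sub-nucleosomal 10-bp ladder. The background (healthy,
#' mostly hematopoietic) source peaks near 166 bp with a faint ladder; a
#' tumor-like source is left-shifted with a stronger ladder and an enlarged
#' di-nucleosome peak.
#'
#' @param mode_length main mode position (bp).
#' @param mode_sd main mode standard deviation (bp).
#' @param dinucleosome_offset offset of the second peak from the mode (bp).
#' @param dinucleosome_weight mixture weight of the di-nucleosome peak.
#' @param dinucleosome_sd standard deviation of the second peak (bp).
#' @param periodicity spacing of the sub-modal comb (bp).
#' @param periodicity_amplitude total mixture weight of the comb.
#' @param periodicity_decay geometric decay of comb bump weights away from the
#'   mode.
#' @param comb_sd standard deviation of each comb bump (bp).
#' @param lengths the length grid.
#' @return numeric probability vector summing to 1, named by length.
#' @examples
#' bg <- build_profile()                      # background-like
#' tm <- build_profile(mode_length = 145, mode_sd = 18,
#'                     dinucleosome_weight = 0.10,
#'                     periodicity_amplitude = 0.22)
#' sum(bg * 30:700) > sum(tm * 30:700)        # tumor is shorter on average
#' @export
build_profile <- function(mode_length = 166, mode_sd = 20,
                          dinucleosome_offset = 167,
                          dinucleosome_weight = 0.04,
                          dinucleosome_sd = 30,
                          periodicity = 10.4,
                          periodicity_amplitude = 0.03,
                          periodicity_decay = 0.75,
                          comb_sd = 2.5,
                          lengths = 30:700) {
  if (dinucleosome_weight < 0 || periodicity_amplitude < 0 ||
      dinucleosome_weight + periodicity_amplitude >= 1)
    stop_fatal("mixture weights must be non-negative and sum below 1")
  if (mode_sd <= 0 || periodicity <= 0) stop_fatal("invalid scale parameter")
  l <- as.numeric(lengths)
  main <- stats::dnorm(l, mode_length, mode_sd)
  main <- main / sum(main)
  p <- (1 - dinucleosome_weight - periodicity_amplitude) * main
  if (dinucleosome_weight > 0) {
    di <- stats::dnorm(l, mode_length + dinucleosome_offset, dinucleosome_sd)
    p <- p + dinucleosome_weight * di / sum(di)
  }
  if (periodicity_amplitude > 0) {
    n_bumps <- floor((mode_length - min(l)) / periodicity)
    j <- seq_len(n_bumps)
    wts <- periodicity_decay^j
    comb <- numeric(length(l))
    for (i in j)
      comb <- comb + wts[i] * stats::dnorm(l, mode_length - i * periodicity,
                                           comb_sd)
    p <- p + periodicity_amplitude * comb / sum(comb)
  }
  p <- p / sum(p)
  names(p) <- as.character(lengths)
  p
}

#' Default tumor-like source profile
#'
#' [build_profile()] with the tumor defaults: left-shifted mode (145 bp),
#' amplified 10-bp ladder below the mode, and an enlarged di-nucleosome peak.
#' @param ... overrides passed to [build_profile()].
#' @export
tumor_profile <- function(...) {
  args <- list(mode_length = 145, mode_sd = 18, dinucleosome_weight = 0.10,
               periodicity_amplitude = 0.22)
  args[names(list(...))] <- list(...)
  do.call(build_profile, args)
}

#' Simulate a cfDNA cohort with known tumor mixing weights
#'
#' Each sample's fragment-length distribution is the mixture
#' `(1 - w) * background + w * tumor` for a per-sample tumor weight `w`;
#' observed counts are a multinomial draw of `depth` fragments from that
#' mixture. The truth table of mixing weights is returned alongside, so
#' downstream weight-recovery can be scored exactly.
#'
#' @param background,tumor source profiles on a common grid (defaults:
#'   [build_profile()] and [tumor_profile()]).
#' @param n_samples cohort size.
#' @param tumor_weights per-sample mixing weights; default uniform on
#'   \[0, 0.9\].
#' @param depth fragments per sample.
#' @param seed master seed (per-sample draw seeds are derived from it).
#' @return list with `matrix` (count matrix, rows = samples) and `truth`
#'   (data.frame `sample`, `tumor_weight`).
#' @export
simulate_cohort <- function(background = build_profile(),
                            tumor = tumor_profile(),
                            n_samples = 50, tumor_weights = NULL,
                            depth = 1e6, seed = NULL) {
  if (length(background) != length(tumor))
    stop_fatal("profiles are on different grids")
  if (depth <= 0) stop_fatal("depth must be positive")
  seeds <- derive_seeds(seed, n_samples + 1L)
  if (is.null(tumor_weights))
    tumor_weights <- with_seed(seeds[[n_samples + 1L]],
                               stats::runif(n_samples, 0, 0.9))
  if (length(tumor_weights) != n_samples)
    stop_fatal("tumor_weights must have length n_samples")
  if (any(tumor_weights < 0 | tumor_weights > 1))
    stop_fatal("tumor weights must lie in [0, 1]")
  rows <- lapply(seq_len(n_samples), function(i) {
    p <- (1 - tumor_weights[i]) * background + tumor_weights[i] * tumor
    with_seed(seeds[[i]], as.numeric(stats::rmultinom(1, depth, p)))
  })
  m <- do.call(rbind, rows)
  labels <- sprintf("sim%02d", seq_len(n_samples))
  dimnames(m) <- list(labels, names(background))
  attr(m, "normalized") <- FALSE
  list(matrix = m,
       truth = data.frame(sample = labels, tumor_weight = tumor_weights))
}

#' Simulate genome-bin histograms from open/closed chromatin sources
#'
#' Each genomic bin mixes an open-chromatin and a closed-chromatin length
#' profile according to a known per-bin openness fraction, mimicking the
#' chromatin-state signal carried by bin-wise fragment-length distributions.
#' Open chromatin yields shorter fragments on average.
#'
#' @param open_profile,closed_profile source profiles (defaults chosen so the
#'   open profile is left-shifted with a stronger sub-modal ladder).
#' @param n_bins number of bins.
#' @param openness per-bin open-chromatin fractions; default uniform on
#'   \[0, 1\].
#' @param depth_per_bin fragments per bin.
#' @param seed master seed.
#' @return list with `matrix` (bins x lengths counts, row names `bin0001`...)
#'   and `truth` (data.frame `bin_id`, `openness`).
#' @export
simulate_binned_cohort <- function(open_profile = build_profile(
                                     mode_length = 160, mode_sd = 22,
                                     periodicity_amplitude = 0.12),
                                   closed_profile = build_profile(
                                     mode_length = 168, mode_sd = 18,
                                     periodicity_amplitude = 0.02),
                                   n_bins = 500, openness = NULL,
                                   depth_per_bin = 1e5, seed = NULL) {
  if (length(open_profile) != length(closed_profile))
    stop_fatal("profiles are on different grids")
  seeds <- derive_seeds(seed, n_bins + 1L)
  if (is.null(openness))
    openness <- with_seed(seeds[[n_bins + 1L]], stats::runif(n_bins))
  if (length(openness) != n_bins) stop_fatal("openness must have length n_bins")
  rows <- lapply(seq_len(n_bins), function(i) {
    p <- openness[i] * open_profile + (1 - openness[i]) * closed_profile
    with_seed(seeds[[i]], as.numeric(stats::rmultinom(1, depth_per_bin, p)))
  })
  m <- do.call(rbind, rows)
  labels <- sprintf("bin%04d", seq_len(n_bins))
  dimnames(m) <- list(labels, names(open_profile))
  attr(m, "normalized") <- FALSE
  list(matrix = m, truth = data.frame(bin_id = labels, openness = openness))
}

#' Simulate a labelled case/control cohort
#'
#' Cases receive tumor weights drawn uniform on `case_weight_range`; controls
#' get weight 0 (pure background). Intended for end-to-end classifier checks
#' where the class signal enters only through the fragment-length mixture.
#'
#' @param n_cases,n_controls class sizes.
#' @param case_weight_range tumor-weight range for cases.
#' @param depth fragments per sample.
#' @param seed master seed.
#' @param ... passed to [simulate_cohort()] (e.g. alternative profiles).
#' @return list with `matrix`, `truth`, and `labels` (factor control/case).
#' @export
simulate_labelled_cohort <- function(n_cases = 25, n_controls = 25,
                                     case_weight_range = c(0.05, 0.6),
                                     depth = 1e5, seed = NULL, ...) {
  seeds <- derive_seeds(seed, 2L)
  w_case <- with_seed(seeds[[1]],
                      stats::runif(n_cases, case_weight_range[1],
                                   case_weight_range[2]))
  w <- c(rep(0, n_controls), w_case)
  sim <- simulate_cohort(n_samples = n_cases + n_controls, tumor_weights = w,
                         depth = depth, seed = seeds[[2]], ...)
  sim$labels <- factor(rep(c("control", "case"), c(n_controls, n_cases)),
                       levels = c("control", "case"))
  sim
}
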