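# Random-pairing permutation control: pseudo-dyad coherence under
# derangements (no mother keeps her own child) and refits of the moderation
# models with the pseudo values.

#' Sample random mother-child pairings
#'
#' Each permutation is a uniformly sampled derangement of the dyads: a
#' one-to-one mother-to-child map with no mother assigned her own child.
#' Derangements preserve each child's appearance count per permutation;
#' \code{method = "independent"} instead draws each mother's child
#' independently (still never her own), for the looser reading of pairing
#' "with a random child from another dyad".
#'
#' @param dyad_ids character vector (>= 3 dyads).
#' @param n_permutations number of pairings (default 100).
#' @param seed integer seed.
#' @param method \code{"derangement"} (default) or \code{"independent"}.
#' @return object of class \code{pairing_scheme}: integer matrix
#'   (permutation x dyad) of assigned child indices, plus ids and seed.
#' @export
random_pairings <- function(dyad_ids, n_permutations = 100L, seed = 1L,
                            method = c("derangement", "independent")) {
  method <- match.arg(method)
  n <- length(dyad_ids)
  if (n < 3) stop("need at least 3 dyads for non-trivial pairings")
  pairings <- with_seed(seed, {
    m <- matrix(NA_integer_, n_permutations, n)
    for (k in seq_len(n_permutations)) {
      if (method == "derangement") {
        repeat {
          p <- sample.int(n)
          if (!any(p == seq_len(n))) break
        }
      } else {
        p <- vapply(seq_len(n), function(i)
          sample(setdiff(seq_len(n), i), 1L), integer(1))
      }
      m[k, ] <- p
    }
    m
  })
  structure(list(pairings = pairings, dyad_ids = dyad_ids,
                 n_permutations = n_permutations, seed = seed, method = method),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat(sprintf("pairing_scheme: %d permutations of %d dyads (%s, seed %d)\n",
              x$n_permutations, length(x$dyad_ids), x$method, x$seed))
  invisible(x)
}

#' Pseudo-dyad coherence under random pairings
#'
#' For each mother, computes the band-of-interest wavelet coherence with the
#' child assigned by each permutation and averages across permutations,
#' yielding one pseudo coherence per mother, region and chromophore. The
#' wavelet transforms and smoothed autospectra of every person are computed
#' once and reused across pairings.
#'
#' @param region_series per-dyad list with \code{mother} and \code{child}
#'   region series (see \code{\link{dyad_coherence}}).
#' @param scheme a \code{\link{random_pairings}} scheme over the same dyads.
#' @param dt sampling interval (default 1 s).
#' @param foi Hz pair.
#' @param coi_policy passed to \code{\link{average_foi}}.
#' @param spec a \code{\link{wavelet_spec}}.
#' @param chromophores chromophores to summarise.
#' @return data.frame: dyad_id (the mother's), region, chromophore,
#'   pseudo_coherence.
#' @export
permuted_coherence <- function(region_series, scheme, dt = 1,
                               foi = c(0.02, 0.1), coi_policy = "exclude",
                               spec = wavelet_spec(),
                               chromophores = c("hbo", "hbr")) {
  ids <- scheme$dyad_ids
  stopifnot(all(ids %in% names(region_series)))
  regions <- names(region_series[[ids[1]]]$mother)
  n <- length(ids)
  # common length across everyone (truncate with a warning on mismatch)
  lens <- unlist(lapply(region_series[ids], function(p)
    lapply(p, function(per) lapply(per, function(r) lapply(r, length)))))
  L <- min(lens)
  if (any(lens != L))
    warning("series length mismatch across dyads; truncating to common length")
  pre <- list()
  for (id in ids) for (p in c("mother", "child")) for (r in regions)
    for (ch in chromophores) {
      x <- region_series[[id]][[p]][[r]][[ch]][seq_len(L)]
      pre[[paste(id, p, r, ch, sep = ".")]] <-
        smooth_wavelet_power(cwt_morlet(x, dt, spec))
    }
  rows <- list()
  for (r in regions) for (ch in chromophores) {
    for (i in seq_len(n)) {
      cm <- pre[[paste(ids[i], "mother", r, ch, sep = ".")]]
      vals <- vapply(seq_len(scheme$n_permutations), function(k) {
        j <- scheme$pairings[k, i]
        cc <- pre[[paste(ids[j], "child", r, ch, sep = ".")]]
        as.numeric(average_foi(wavelet_coherence(cm, cc, spec = spec),
                               foi, coi_policy))
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(dyad_id = ids[i], region = r, chromophore = ch,
                   pseudo_coherence = mean(vals))
    }
  }
  do.call(rbind, rows)
}

#' Refit moderation models with pseudo-pair coherence
#'
#' Joins the permutation-averaged pseudo coherence to the behavioral table by
#' the mother's dyad id and refits the same moderation model(s) that were run
#' with true-pair coherence, for side-by-side comparison: interactions driven
#' by genuine dyadic synchrony should vanish under random pairing.
#'
#' @param behavior behavioral data.frame keyed by dyad_id.
#' @param pseudo result of \code{\link{permuted_coherence}}.
#' @param iv focal predictor column.
#' @param covariates covariate columns.
#' @param outcome outcome column.
#' @param region,chromophore which pseudo summary to use.
#' @param alpha significance level.
#' @return a \code{\link{fit_moderation}} result with the pseudo moderator.
#' @export
permutation_check <- function(behavior, pseudo, iv,
                              covariates = character(),
                              outcome = "dysregulation",
                              region = "left_dlPFC", chromophore = "hbo",
                              alpha = 0.05) {
  sel <- pseudo[pseudo$region == region & pseudo$chromophore == chromophore, ]
  d <- merge(behavior, sel[c("dyad_id", "pseudo_coherence")], by = "dyad_id")
  fit_moderation(d, iv = iv, moderator = "pseudo_coherence",
                 covariates = covariates, outcome = outcome, alpha = alpha)
}
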