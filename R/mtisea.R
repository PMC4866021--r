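# MTI-set enrichment analysis: a GSEA-style weighted Kolmogorov-Smirnov
# running sum over a ranked target list, with gene-set-resampling permutations
# for the normalized enrichment score and a pooled-permutation FDR q-value.

#' Prepare a ranked target list
#'
#' Orders a `(accession, rank_value)` table by descending rank value with a
#' stable sort (ties keep input order) and drops duplicated accessions,
#' keeping the first occurrence with a warning.
#'
#' @param ranked A data frame with columns `accession` and `rank_value`.
#' @return A tibble in final ranking order.
#' @export
prepare_ranked_list <- function(ranked) {
  stopifnot(all(c("accession", "rank_value") %in% names(ranked)))
  ranked <- tibble::as_tibble(ranked[c("accession", "rank_value")])
  ranked$rank_value <- as.numeric(ranked$rank_value)
  dup <- duplicated(ranked$accession)
  if (any(dup)) {
    rlang::warn(sprintf(
      "%d duplicated accession(s) in the ranked list; keeping first occurrence.",
      sum(dup)))
    ranked <- ranked[!dup, ]
  }
  if (nrow(ranked) < 2) rlang::abort("Ranked list needs at least 2 entries.")
  ranked[order(-ranked$rank_value), ]  # stable: radix/shell keep input order on ties
}

#' Read a ranked target list
#'
#' Tab-separated with a header: `accession`, `rank_value`. The ranking value's
#' origin is arbitrary (expression statistic, network connectivity, ...);
#' negative values are allowed.
#'
#' @param path Path to the ranked TSV.
#' @return A prepared ranked tibble (see [prepare_ranked_list()]).
#' @export
read_ranked_list <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (!all(c("accession", "rank_value") %in% names(tab))) {
    names(tab)[1:2] <- c("accession", "rank_value")
  }
  prepare_ranked_list(tab)
}

# fast ES kernel shared by the observed statistic and the permutations:
# given hit positions within a list of length n, hit weights |r|^p (absw),
# return the running sum's signed extremum and its position.
# Hits step up by absw/N_R, misses step down by 1/(n - n_h); the increments
# sum to zero so the walk always returns to 0 at position n.
es_kernel <- function(hit_idx, absw, n) {
  n_h <- length(hit_idx)
  n_r <- sum(absw[hit_idx])
  step <- numeric(n)
  step[] <- -1 / (n - n_h)
  if (n_r > 0) {
    step[hit_idx] <- absw[hit_idx] / n_r
  } else {
    # all hit weights zero (possible at p >= 1 with zero rank values):
    # fall back to equal hit weights, i.e. the unweighted statistic
    step[hit_idx] <- 1 / n_h
  }
  cs <- cumsum(step)
  # earliest position within 1e-12 of the maximal deviation wins, so exact
  # arithmetic ties (common at p = 0, where the sums are small rationals)
  # resolve deterministically instead of by accumulation noise
  a <- abs(cs)
  pos <- which(a >= max(a) - 1e-12)[1]
  list(es = cs[pos], position = pos, running_sum = cs)
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list accumulating a running sum: positions whose
#' accession belongs to the set (hits) step up by `|rank_value|^p / N_R`
#' (`N_R` = sum of `|rank_value|^p` over the hits), misses step down by
#' `1 / (N - N_H)`. The enrichment score is the signed value of maximal
#' absolute deviation from zero; at ties (within 1e-12) the first extremal
#' position wins.
#' The walk ends at zero by construction. `p = 0` gives the classic
#' unweighted Kolmogorov-Smirnov-like statistic; the default `p = 1` weights
#' hits by their ranking value.
#'
#' The set must intersect the ranked list (`N_H > 0`) and must not cover it
#' entirely (`N_H < N`, or the miss step is undefined).
#'
#' @param ranked Ranked tibble (see [prepare_ranked_list()]); row order is the
#'   ranking order.
#' @param set_members Character vector of accessions.
#' @param weight_p Hit-weight exponent `p >= 0`.
#' @return A list: `es`, `es_position`, `running_sum` (length `N`),
#'   `hits` (logical length `N`), `n_hits`.
#' @examples
#' ranked <- tibble::tibble(accession = c("a", "b", "c", "d"),
#'                          rank_value = c(4, 3, 2, 1))
#' compute_es(ranked, c("a", "c"), weight_p = 1)$es  # 2/3
#' @export
compute_es <- function(ranked, set_members, weight_p = 1) {
  n <- nrow(ranked)
  hits <- ranked$accession %in% set_members
  n_h <- sum(hits)
  if (n_h == 0) rlang::abort("Set has no members in the ranked list.")
  if (n_h == n) {
    rlang::abort("Set covers the whole ranked list; miss step undefined.")
  }
  absw <- abs(ranked$rank_value)^weight_p
  if (weight_p == 0) absw <- rep(1, n)  # 0^0 := 1 for unweighted scoring
  hit_idx <- which(hits)
  if (sum(absw[hit_idx]) == 0 && weight_p > 0) {
    rlang::warn("All hit weights are zero; falling back to unweighted hits.")
  }
  k <- es_kernel(hit_idx, absw, n)
  list(es = k$es, es_position = k$position, running_sum = k$running_sum,
       hits = hits, n_hits = n_h)
}

#' Leading-edge members of an enrichment score
#'
#' The core targets that drive the score: for a positive ES, the set members
#' at or before the running-sum extremum; for a negative ES, the members at
#' or after it. (An ES of exactly zero follows the positive rule.)
#'
#' @param ranked Ranked tibble.
#' @param es_result Result of [compute_es()].
#' @return Character vector of accessions.
#' @export
leading_edge <- function(ranked, es_result) {
  pos <- which(es_result$hits)
  keep <- if (es_result$es >= 0) {
    pos <= es_result$es_position
  } else {
    pos >= es_result$es_position
  }
  ranked$accession[pos[keep]]
}

#' Permutation-normalized enrichment score
#'
#' Normalizes the observed ES against a null built by gene-set resampling:
#' each permutation draws `N_H` accessions uniformly without replacement from
#' the ranked list (the set size is kept constant) and the ES is recomputed.
#' `NES = ES / mean(|permutation ES|)` over the permutations whose sign equals
#' the observed sign; an ES of 0 gives NES 0. If no same-sign permutation
#' exists the NES is undefined and reported as `NA` with a warning.
#'
#' @param ranked Ranked tibble.
#' @param set_members Character vector of accessions.
#' @param es Observed enrichment score (from [compute_es()]).
#' @param weight_p Hit-weight exponent.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed (the global RNG state is restored).
#' @return A list: `nes`, `perm_es` (length `n_perm`), `perm_nes`
#'   (each permutation ES normalized by the same-sign permutation mean, for
#'   FDR pooling).
#' @export
compute_nes <- function(ranked, set_members, es, weight_p = 1,
                        n_perm = 1000L, seed = NULL) {
  stopifnot(n_perm >= 1)
  n <- nrow(ranked)
  n_h <- sum(ranked$accession %in% set_members)
  absw <- abs(ranked$rank_value)^weight_p
  if (weight_p == 0) absw <- rep(1, n)
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      es_kernel(sample.int(n, n_h), absw, n)$es
    }, numeric(1))
  }
  perm_es <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  normalize_es(es, perm_es)
}

# shared ES -> NES normalization: sign-stratified by the permutation means
normalize_es <- function(es, perm_es) {
  mean_pos <- mean(abs(perm_es[perm_es > 0]))
  mean_neg <- mean(abs(perm_es[perm_es < 0]))
  norm1 <- function(x) {
    if (x == 0) return(0)
    m <- if (x > 0) mean_pos else mean_neg
    if (is.nan(m) || m == 0) return(NA_real_)
    x / m
  }
  nes <- norm1(es)
  if (is.na(nes)) {
    rlang::warn("No same-sign permutation ES; NES undefined for this set.")
  }
  perm_nes <- vapply(perm_es, norm1, numeric(1))
  list(nes = nes, perm_es = perm_es, perm_nes = perm_nes)
}

#' FDR q-values from pooled permutation NES
#'
#' For a set with observed `NES* >= 0`,
#' `q = [fraction of pooled positive-stratum permutation NES >= NES*] /
#' [fraction of observed non-negative NES >= NES*]`, clipped to `[0, 1]`;
#' mirrored for negative `NES*`. An empty permutation stratum (zero
#' denominator in the estimated tail) gives `q = 0` by convention. Sets with
#' undefined NES get `NA` and are excluded from the strata.
#'
#' @param observed_nes Numeric vector of per-set NES values (may contain
#'   `NA`).
#' @param perm_nes Numeric vector of pooled permutation NES values across all
#'   sets.
#' @return Numeric vector of q-values aligned with `observed_nes`.
#' @export
compute_fdr <- function(observed_nes, perm_nes) {
  perm_nes <- perm_nes[!is.na(perm_nes)]
  obs <- observed_nes[!is.na(observed_nes)]
  perm_pos <- perm_nes[perm_nes >= 0]
  perm_neg <- perm_nes[perm_nes < 0]
  obs_pos <- obs[obs >= 0]
  obs_neg <- obs[obs < 0]
  q1 <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- if (length(perm_pos) == 0) 0 else mean(perm_pos >= x)
      den <- if (length(obs_pos) == 0) 0 else mean(obs_pos >= x)
    } else {
      num <- if (length(perm_neg) == 0) 0 else mean(perm_neg <= x)
      den <- if (length(obs_neg) == 0) 0 else mean(obs_neg <= x)
    }
    if (den == 0) return(0)
    min(1, num / den)
  }
  vapply(observed_nes, q1, numeric(1))
}

#' MTI-set enrichment analysis
#'
#' Scores every eligible MTI set against a user-ranked target list: weighted
#' running-sum enrichment score, gene-set-resampling NES, pooled-permutation
#' FDR q-value, and leading-edge extraction. Set members absent from the
#' ranked list are dropped first; sets smaller than `min_set_size` after
#' intersection, empty sets, and sets covering the whole list are skipped
#' with a warning.
#'
#' @param sets MTI set tibble from [build_mti_sets()], or a named list of
#'   accession vectors.
#' @param ranked Ranked tibble (see [prepare_ranked_list()]).
#' @param weight_p Hit-weight exponent (default 1, the weighted statistic;
#'   0 gives the unweighted one).
#' @param n_perm Permutations per set (default 1000).
#' @param min_set_size Minimal post-intersection set size (default 3).
#' @param seed Optional integer seed; fixed seed gives bit-identical results.
#' @return An object of class `mtisea_result`: `ranking` (tibble sorted by
#'   descending NES, then q, then set size: `mirna_key`, `set_size`, `es`,
#'   `nes`, `fdr_q`, `es_position`, `leading_edge_size`), `traces` (named list
#'   of per-set hit tables: `accession`, `index`, `rank_value`, `running_es`,
#'   `leading_edge`), `running_sums` (named list of full length-N curves),
#'   `leading_edges` (named list of accession vectors), `skipped` (tibble with
#'   reasons), and the parameters.
#' @export
run_mtisea <- function(sets, ranked, weight_p = 1, n_perm = 1000L,
                       min_set_size = 3L, seed = NULL) {
  members <- as_member_list(sets)
  n <- nrow(ranked)

  in_list <- purrr::map(members, function(m) {
    intersect(unique(m), ranked$accession)
  })
  sizes <- lengths(in_list)
  reason <- dplyr::case_when(
    sizes == 0 ~ "no members in ranked list",
    sizes < min_set_size ~ "below min_set_size",
    sizes == n ~ "covers whole ranked list",
    TRUE ~ NA_character_
  )
  skipped <- tibble::tibble(mirna_key = names(members),
                            reason = reason)[!is.na(reason), ]
  if (nrow(skipped) > 0) {
    rlang::warn(sprintf("Skipped %d ineligible set(s).", nrow(skipped)))
  }
  eligible <- names(members)[is.na(reason)]
  if (length(eligible) == 0) {
    rlang::warn("No eligible MTI sets; empty enrichment output.")
    return(empty_mtisea_result(weight_p, n_perm, min_set_size, seed, skipped))
  }

  run <- function() {
    purrr::map(eligible, function(key) {
      esr <- compute_es(ranked, in_list[[key]], weight_p)
      nesr <- compute_nes(ranked, in_list[[key]], esr$es, weight_p,
                          n_perm = n_perm, seed = NULL)
      le <- leading_edge(ranked, esr)
      list(key = key, esr = esr, nesr = nesr, le = le)
    })
  }
  fits <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  observed_nes <- purrr::map_dbl(fits, function(f) f$nesr$nes)
  pooled <- unlist(purrr::map(fits, function(f) f$nesr$perm_nes))
  fdr_q <- compute_fdr(observed_nes, pooled)

  ranking <- tibble::tibble(
    mirna_key = purrr::map_chr(fits, "key"),
    set_size = unname(sizes[eligible]),
    es = purrr::map_dbl(fits, function(f) f$esr$es),
    nes = observed_nes,
    fdr_q = fdr_q,
    es_position = purrr::map_int(fits, function(f) f$esr$es_position),
    leading_edge_size = purrr::map_int(fits, function(f) length(f$le))
  ) |>
    dplyr::arrange(dplyr::desc(.data$nes), .data$fdr_q,
                   dplyr::desc(.data$set_size), .data$mirna_key)

  traces <- purrr::map(fits, function(f) {
    idx <- which(f$esr$hits)
    tibble::tibble(
      accession = ranked$accession[idx],
      index = idx,
      rank_value = ranked$rank_value[idx],
      running_es = f$esr$running_sum[idx],
      leading_edge = ranked$accession[idx] %in% f$le
    )
  })
  names(traces) <- ranking_names <- purrr::map_chr(fits, "key")
  running_sums <- purrr::map(fits, function(f) f$esr$running_sum)
  names(running_sums) <- ranking_names
  leading_edges <- purrr::map(fits, "le")
  names(leading_edges) <- ranking_names

  structure(
    list(ranking = ranking, traces = traces, running_sums = running_sums,
         leading_edges = leading_edges, skipped = skipped,
         n_ranked = n, weight_p = weight_p, n_perm = as.integer(n_perm),
         min_set_size = as.integer(min_set_size), seed = seed),
    class = "mtisea_result"
  )
}

as_member_list <- function(sets) {
  if (inherits(sets, "data.frame")) {
    stopifnot(all(c("mirna_key", "targets") %in% names(sets)))
    members <- purrr::map(sets$targets, function(t) unique(t$accession))
    names(members) <- sets$mirna_key
    members
  } else {
    stopifnot(is.list(sets), !is.null(names(sets)))
    sets
  }
}

empty_mtisea_result <- function(weight_p, n_perm, min_set_size, seed, skipped) {
  structure(
    list(
      ranking = tibble::tibble(mirna_key = character(), set_size = integer(),
                               es = numeric(), nes = numeric(),
                               fdr_q = numeric(), es_position = integer(),
                               leading_edge_size = integer()),
      traces = list(), running_sums = list(), leading_edges = list(),
      skipped = skipped, n_ranked = NA_integer_, weight_p = weight_p,
      n_perm = as.integer(n_perm), min_set_size = as.integer(min_set_size),
      seed = seed
    ),
    class = "mtisea_result"
  )
}

#' @export
print.mtisea_result <- function(x, ...) {
  cat(sprintf(
    "<mtisea_result> %d set(s) scored against %s ranked targets (p = %g, %d permutations)\n",
    nrow(x$ranking), format(x$n_ranked), x$weight_p, x$n_perm))
  if (nrow(x$skipped) > 0) cat(sprintf("  %d set(s) skipped\n", nrow(x$skipped)))
  print(x$ranking, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enrichment result
#'
#' @param x An `mtisea_result`.
#' @param ... Unused.
#' @return The per-set ranking tibble.
#' @method tidy mtisea_result
#' @export
tidy.mtisea_result <- function(x, ...) x$ranking

#' One-row summary of an enrichment result
#'
#' @param x An `mtisea_result`.
#' @param ... Unused.
#' @return A one-row tibble: sets tested/skipped, list length, parameters,
#'   and the number of sets with `fdr_q < 0.05`.
#' @method glance mtisea_result
#' @export
glance.mtisea_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$ranking),
    n_skipped = nrow(x$skipped),
    n_ranked = x$n_ranked,
    weight_p = x$weight_p,
    n_perm = x$n_perm,
    min_set_size = x$min_set_size,
    n_sig_q05 = sum(x$ranking$fdr_q < 0.05, na.rm = TRUE)
  )
}
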