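# Connectivity-map style matching of extreme signatures against ranked
# disease profiles: bidirectional KS enrichment score, Total Matching Score
# (TMS) and its permutation null.

# KS enrichment from sorted 1-based hit positions V (length tprime) in a
# profile of n genes:
#   a = max_j [ j/t' - V(j)/n ],  b = max_j [ V(j)/n - (j-1)/t' ]
# return a if a > b else -b.
.es_from_positions <- function(V, n) {
  tprime <- length(V)
  j <- seq_len(tprime)
  a <- max(j / tprime - V / n)
  b <- max(V / n - (j - 1) / tprime)
  if (a > b) a else -b
}

#' KS enrichment score of a gene set against a ranked profile
#'
#' The signed Kolmogorov-Smirnov statistic of the Connectivity Map: positive
#' when the set concentrates at the top of the ranking (up-regulated end),
#' negative when it concentrates at the bottom. Set members absent from the
#' profile are dropped (with a message) and the retained size is used in the
#' denominators.
#'
#' @param profile A [ranked_profile()].
#' @param geneset Character vector of gene symbols.
#' @param quiet Suppress the dropped-genes message.
#' @return Numeric in `[-1, 1]`.
#' @export
enrichment_score <- function(profile, geneset, quiet = FALSE) {
  stopifnot(inherits(profile, "ranked_profile"))
  pos <- match(unique(as.character(geneset)), profile$gene)
  dropped <- sum(is.na(pos))
  pos <- sort(pos[!is.na(pos)])
  if (dropped > 0L && !quiet) {
    message(dropped, " gene(s) absent from the profile dropped")
  }
  if (length(pos) == 0L) {
    stop("gene set has no members in the profile")
  }
  .es_from_positions(pos, nrow(profile))
}

#' Total Matching Score of an extreme signature against a disease profile
#'
#' `TMS = (ES(top) - ES(bottom)) / 2`, in `[-1, 1]`. A positive score means
#' the herb's perturbation mimics the disease ranking (its activated genes
#' sit among the disease's up-regulated genes and vice versa); a negative
#' score means the herb reverses the disease pattern, the therapeutic
#' direction.
#'
#' @param profile A [ranked_profile()].
#' @param sig An [extreme_signature()].
#' @param quiet Suppress dropped-genes messages.
#' @return Object of class `match_result`: list with `ms_top`, `ms_bottom`,
#'   `tms`, `t`, `n_profile`, `genes_used_top`, `genes_used_bottom`.
#' @export
total_matching_score <- function(profile, sig, quiet = TRUE) {
  stopifnot(inherits(profile, "ranked_profile"),
            inherits(sig, "extreme_signature"))
  n <- nrow(profile)
  pos_top <- match(sig$top, profile$gene)
  pos_bot <- match(sig$bottom, profile$gene)
  used_top <- sum(!is.na(pos_top))
  used_bot <- sum(!is.na(pos_bot))
  if (!quiet && (used_top < sig$t || used_bot < sig$t)) {
    message((sig$t - used_top) + (sig$t - used_bot),
            " signature gene(s) absent from the profile dropped")
  }
  if (used_top == 0L || used_bot == 0L) {
    stop("extreme set with no members in the profile (top: ", used_top,
         ", bottom: ", used_bot, ")")
  }
  ms_top <- .es_from_positions(sort(pos_top[!is.na(pos_top)]), n)
  ms_bot <- .es_from_positions(sort(pos_bot[!is.na(pos_bot)]), n)
  structure(
    list(ms_top = ms_top, ms_bottom = ms_bot,
         tms = (ms_top - ms_bot) / 2, t = sig$t, n_profile = n,
         genes_used_top = used_top, genes_used_bottom = used_bot),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("TMS = %.4f (ES top = %.4f, ES bottom = %.4f, t = %d, n = %d)\n",
              x$tms, x$ms_top, x$ms_bottom, x$t, x$n_profile))
  invisible(x)
}

# TMS of a random signature drawn as 2t distinct profile positions,
# first t = top, last t = bottom. Internal fast path for the null.
.random_tms <- function(n, t) {
  idx <- sample.int(n, 2L * t)
  ms_top <- .es_from_positions(sort.int(idx[seq_len(t)]), n)
  ms_bot <- .es_from_positions(sort.int(idx[(t + 1L):(2L * t)]), n)
  (ms_top - ms_bot) / 2
}

#' Permutation p-value for a herb-disease match
#'
#' Draws `n_perm` random extreme signatures of the same size `t` from the
#' profile's gene universe (2t distinct genes split into random top/bottom
#' halves), computes each random TMS, and reports
#' `p = N / n_perm` where `N` counts permutations with
#' `|TMS_perm| >= |TMS_0|` (a two-sided test on the absolute score). `p` can
#' be exactly 0 when no permutation reaches the observed score; the `note`
#' field then records the resolution bound `< 1/n_perm`.
#'
#' @param profile A [ranked_profile()].
#' @param sig An [extreme_signature()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed; the result is fully reproducible
#'   given the seed.
#' @return Object of class `permutation_result`: list with `tms0`, `n_perm`,
#'   `n_extreme`, `pvalue`, `seed`, `note`.
#' @export
permutation_pvalue <- function(profile, sig, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(profile, "ranked_profile"),
            inherits(sig, "extreme_signature"))
  n <- nrow(profile)
  t <- sig$t
  if (2L * t > n) {
    stop("profile too small for t = ", t, " (need ", 2L * t,
         " genes, have ", n, ")")
  }
  tms0 <- total_matching_score(profile, sig)$tms
  run <- function() {
    hits <- 0L
    thr <- abs(tms0)
    for (i in seq_len(n_perm)) {
      if (abs(.random_tms(n, t)) >= thr) hits <- hits + 1L
    }
    hits
  }
  N <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- N / n_perm
  structure(
    list(tms0 = tms0, n_perm = as.integer(n_perm), n_extreme = N,
         pvalue = p, seed = seed,
         note = if (N == 0L) sprintf("< %g", 1 / n_perm) else NA_character_),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("TMS0 = %.4f, p = %.4g (N = %d / %d)\n",
              x$tms0, x$pvalue, x$n_extreme, x$n_perm))
  invisible(x)
}

#' Score every signature against every profile
#'
#' Computes the Total Matching Score (and optionally a permutation p-value)
#' for the full cartesian product of extreme signatures and disease
#' profiles: exactly `length(signatures) * length(profiles)` rows. A pair
#' whose scoring fails (e.g. no signature gene present in the profile) is
#' returned as a flagged row with `NA` scores rather than aborting the run.
#'
#' @param signatures List of [extreme_signature()] objects.
#' @param profiles List of [ranked_profile()] objects.
#' @param n_perm Permutations per pair; 0 skips the permutation test.
#' @param seed Optional integer seed for the permutation draws.
#' @param alpha Significance threshold applied to the permutation p-value.
#' @return Data frame with one row per (signature, profile) pair: columns
#'   `subject_id`, `disease_id`, `t`, `ms_top`, `ms_bottom`, `tms`,
#'   `pvalue`, `n_extreme`, `genes_used_top`, `genes_used_bottom`,
#'   `significant`, `error`.
#' @export
score_all <- function(signatures, profiles, n_perm = 0, seed = NULL,
                      alpha = 0.05) {
  if (length(signatures) == 0L) stop("no signatures supplied")
  if (length(profiles) == 0L) stop("no profiles supplied")
  sig_ids <- vapply(signatures, function(s) s$id, character(1))
  prof_ids <- vapply(seq_along(profiles), function(k) {
    id <- attr(profiles[[k]], "id")
    if (is.null(id)) paste0("profile_", k) else id
  }, character(1))

  n_pairs <- length(signatures) * length(profiles)
  out <- data.frame(
    subject_id = rep(sig_ids, times = length(profiles)),
    disease_id = rep(prof_ids, each = length(signatures)),
    t = NA_integer_, ms_top = NA_real_, ms_bottom = NA_real_,
    tms = NA_real_, pvalue = NA_real_, n_extreme = NA_integer_,
    genes_used_top = NA_integer_, genes_used_bottom = NA_integer_,
    significant = NA, error = NA_character_,
    stringsAsFactors = FALSE
  )

  row <- 0L
  for (pk in seq_along(profiles)) {
    profile <- profiles[[pk]]
    for (sk in seq_along(signatures)) {
      row <- row + 1L
      res <- tryCatch(
        total_matching_score(profile, signatures[[sk]]),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        out$error[row] <- conditionMessage(res)
        next
      }
      out$t[row] <- res$t
      out$ms_top[row] <- res$ms_top
      out$ms_bottom[row] <- res$ms_bottom
      out$tms[row] <- res$tms
      out$genes_used_top[row] <- res$genes_used_top
      out$genes_used_bottom[row] <- res$genes_used_bottom
      if (n_perm > 0) {
        pair_seed <- if (is.null(seed)) NULL else (seed + row) %% .Machine$integer.max
        perm <- permutation_pvalue(profile, signatures[[sk]],
                                   n_perm = n_perm, seed = pair_seed)
        out$pvalue[row] <- perm$pvalue
        out$n_extreme[row] <- perm$n_extreme
        out$significant[row] <- perm$pvalue < alpha
      }
    }
  }
  stopifnot(row == n_pairs)
  out
}
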