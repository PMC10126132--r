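#' Multi-tissue binary microRNA profile set
#'
#' Container for per-individual binary microRNA profiles measured in several
#' airway sampling levels (e.g. EBC, bronchoalveolar lavage BAL, bronchial
#' brush BB, sputum SP, mouthwash MW). Stored as a 3-d array
#' individuals x tissues x microRNAs with cells in `{1, 0, NA}`.
#'
#' @param calls either such a 3-d array (with dimnames), or a long-format
#'   data frame with columns `individual_id`, `tissue`, `mir_id`, `call`.
#' @return An object of class `tissue_profile_set` with elements
#'   `individuals`, `tissues`, `mirs`, `profiles` (the array).
#' @export
tissue_profile_set <- function(calls) {
  if (is.array(calls) && length(dim(calls)) == 3L) {
    dn <- dimnames(calls)
    if (is.null(dn) || any(vapply(dn, is.null, logical(1L))))
      stop("profile array needs full dimnames (individuals, tissues, mirs)")
    arr <- calls
  } else if (is.data.frame(calls)) {
    need <- c("individual_id", "tissue", "mir_id", "call")
    if (!all(need %in% names(calls)))
      stop("long profile table needs columns ", paste(need, collapse = ", "))
    inds <- unique(as.character(calls$individual_id))
    tis <- unique(as.character(calls$tissue))
    mirs <- unique(normalize_mir_id(calls$mir_id))
    arr <- array(NA_integer_, dim = c(length(inds), length(tis), length(mirs)),
                 dimnames = list(inds, tis, mirs))
    arr[cbind(match(as.character(calls$individual_id), inds),
              match(as.character(calls$tissue), tis),
              match(normalize_mir_id(calls$mir_id), mirs))] <-
      as.integer(calls$call)
  } else stop("calls must be a 3-d array or a long-format data frame")
  bad <- !(arr %in% c(0L, 1L, NA))
  if (any(bad)) stop("profile calls must be 1, 0 or NA")
  structure(list(individuals = dimnames(arr)[[1L]],
                 tissues = dimnames(arr)[[2L]],
                 mirs = dimnames(arr)[[3L]],
                 profiles = arr),
            class = "tissue_profile_set")
}

#' @export
print.tissue_profile_set <- function(x, ...) {
  cat(sprintf("tissue_profile_set: %d individuals x %d tissues x %d microRNAs\n",
              length(x$individuals), length(x$tissues), length(x$mirs)))
  cat("  tissues:", paste(x$tissues, collapse = ", "), "\n")
  cat(sprintf("  missing cells: %d\n", sum(is.na(x$profiles))))
  invisible(x)
}

#' Hamming distance between two binary microRNA profiles
#'
#' Number of microRNAs at which two equal-length binary profiles are
#' discordant. Positions missing in either profile are excluded; the number
#' of positions actually compared is attached as attribute `"n_compared"`.
#'
#' @param profile_a,profile_b binary vectors (values 1, 0 or `NA`) of equal
#'   length.
#' @return Integer distance with attribute `n_compared`.
#' @export
#' @examples
#' hamming(c(1, 0, 1), c(1, 1, 0))   # 2
hamming <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  ok <- !is.na(profile_a) & !is.na(profile_b)
  structure(as.integer(sum(profile_a[ok] != profile_b[ok])),
            n_compared = as.integer(sum(ok)))
}

#' @keywords internal
#' Cross-individual Hamming matrix between two tissues.
#' D[i, j] = Hamming(profile of individual i in tissue_a,
#'                   profile of individual j in tissue_b), pairwise-complete.
tissue_pair_distances <- function(set, tissue_a, tissue_b, strict = FALSE) {
  stopifnot(inherits(set, "tissue_profile_set"))
  for (t in c(tissue_a, tissue_b))
    if (!t %in% set$tissues) stop(sprintf("tissue '%s' not in profile set", t))
  A <- set$profiles[, tissue_a, , drop = TRUE]
  B <- set$profiles[, tissue_b, , drop = TRUE]
  if (is.null(dim(A))) { A <- matrix(A, nrow = 1L); B <- matrix(B, nrow = 1L) }
  usable <- rowSums(!is.na(A)) > 0L & rowSums(!is.na(B)) > 0L
  if (strict)
    usable <- usable & rowSums(is.na(A)) == 0L & rowSums(is.na(B)) == 0L
  if (!any(usable))
    stop(sprintf("no individual has usable profiles for both '%s' and '%s'",
                 tissue_a, tissue_b))
  A <- A[usable, , drop = FALSE]; B <- B[usable, , drop = FALSE]
  okA <- !is.na(A); okB <- !is.na(B)
  A0 <- A; A0[!okA] <- 0L; B0 <- B; B0[!okB] <- 0L
  # discordant = a(1-b) + (1-a)b over jointly observed positions
  D <- A0 %*% t((1 - B0) * okB) + ((1 - A0) * okA) %*% t(B0)
  Ncmp <- okA %*% t(okB)
  list(D = round(D), n_compared = Ncmp,
       individuals = set$individuals[usable],
       skipped = set$individuals[!usable])
}

#' Airway-topography similarity statistic SH
#'
#' Sum over individuals of the Hamming distance between the individual's
#' binary microRNA profiles in two tissue types. Small SH means the two
#' tissues carry similar microRNA profiles within individuals. Individuals
#' lacking a usable profile in either tissue are skipped and reported in the
#' `"skipped"` attribute; missing calls are excluded pairwise (or, with
#' `strict = TRUE`, any individual with a missing call is dropped).
#'
#' @param set a [tissue_profile_set()].
#' @param tissue_a,tissue_b tissue codes present in `set`.
#' @param strict drop individuals with any missing call. Default `FALSE`.
#' @return Integer SH with attributes `per_individual` (named vector of
#'   Hamming contributions), `n_individuals`, and `skipped`.
#' @export
similarity_statistic <- function(set, tissue_a, tissue_b, strict = FALSE) {
  dd <- tissue_pair_distances(set, tissue_a, tissue_b, strict = strict)
  per <- stats::setNames(as.integer(diag(dd$D)), dd$individuals)
  structure(as.integer(sum(per)),
            per_individual = per,
            n_individuals = length(per),
            skipped = dd$skipped)
}

#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Permutation test for within-individual tissue similarity
#'
#' Tests whether two tissue types' binary microRNA profiles are more similar
#' within individuals than between random individuals. The null distribution
#' is generated by permuting the assignment of `tissue_b` profiles to
#' individual labels while holding `tissue_a` fixed (distributionally
#' identical, under relabelling, to independently permuting the profiles
#' within each tissue type). The test is one-sided towards small SH;
#' permuted statistics equal to the observed SH count as "as or more
#' similar" (conservative).
#'
#' With `n` usable individuals at or below `exhaustive_threshold`, all `n!`
#' relabellings are enumerated and the p-value is the exact fraction of
#' permutations (identity included) with SH at or below the observed value.
#' Otherwise `n_permutations` Monte-Carlo draws are taken and the add-one
#' estimator `(b + 1) / (B + 1)` is reported, so the p-value is never zero;
#' the plain proportion `b / B` is also retained in the result.
#'
#' @param set a [tissue_profile_set()].
#' @param tissue_a,tissue_b tissue codes.
#' @param n_permutations Monte-Carlo permutation count (>= 1). Default 1000.
#' @param seed integer seed for the Monte-Carlo draw; recorded in the result.
#' @param exhaustive_threshold enumerate all permutations when the number of
#'   usable individuals does not exceed this. Default 7.
#' @param strict see [similarity_statistic()].
#' @return Object of class `topo_permtest`: `observed_sh`, `p_value`,
#'   `n_permutations`, `n_as_or_more_similar`, `p_plain` (Monte-Carlo only),
#'   `exhaustive`, `tissue_pair`, `seed`, `n_individuals`, `per_individual`,
#'   `skipped`.
#' @export
#' @examples
#' sim <- generate_tissue_profiles(seed = 7)
#' permutation_test(sim$set, "EBC", "BAL", n_permutations = 1000, seed = 1)
permutation_test <- function(set, tissue_a, tissue_b,
                             n_permutations = 1000L, seed = NULL,
                             exhaustive_threshold = 7L, strict = FALSE) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  dd <- tissue_pair_distances(set, tissue_a, tissue_b, strict = strict)
  D <- dd$D
  n <- nrow(D)
  observed <- sum(diag(D))
  idx <- seq_len(n)
  if (n <= exhaustive_threshold) {
    perms <- all_permutations(n)
    stat <- vapply(seq_len(nrow(perms)), function(r)
      sum(D[cbind(idx, perms[r, ])]), numeric(1L))
    b <- sum(stat <= observed)
    res <- list(observed_sh = as.integer(observed),
                n_permutations = nrow(perms),
                n_as_or_more_similar = as.integer(b),
                p_value = b / nrow(perms),
                p_plain = b / nrow(perms),
                exhaustive = TRUE, seed = seed)
  } else {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    B <- as.integer(n_permutations)
    for (r in seq_len(B)) {
      p <- sample.int(n)
      if (sum(D[cbind(idx, p)]) <= observed) b <- b + 1L
    }
    res <- list(observed_sh = as.integer(observed),
                n_permutations = B,
                n_as_or_more_similar = b,
                p_value = (b + 1) / (B + 1),
                p_plain = b / B,
                exhaustive = FALSE, seed = seed)
  }
  res$tissue_pair <- c(tissue_a, tissue_b)
  res$n_individuals <- n
  res$per_individual <- stats::setNames(as.integer(diag(D)), dd$individuals)
  res$skipped <- dd$skipped
  class(res) <- "topo_permtest"
  res
}

#' @export
print.topo_permtest <- function(x, ...) {
  cat("Airway-topography similarity permutation test\n")
  cat(sprintf("  tissues: %s vs %s   (%d individuals%s)\n",
              x$tissue_pair[1L], x$tissue_pair[2L], x$n_individuals,
              if (length(x$skipped)) paste0("; skipped: ",
                                            paste(x$skipped, collapse = ",")) else ""))
  cat(sprintf("  observed SH = %d\n", x$observed_sh))
  if (x$exhaustive) {
    cat(sprintf("  exact p = %.4g  (%d of %d enumerated permutations as or more similar)\n",
                x$p_value, x$n_as_or_more_similar, x$n_permutations))
  } else {
    cat(sprintf("  Monte-Carlo p = %.4g  (add-one, B = %d, seed = %s; plain %.4g)\n",
                x$p_value, x$n_permutations,
                if (is.null(x$seed)) "unset" else x$seed, x$p_plain))
  }
  invisible(x)
}
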