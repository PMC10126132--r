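#' Scoring configuration for qualitative qPCR calls
#'
#' Bundles the thresholds used to turn instrument-reported Ct and melt
#' temperature (Tm) into qualitative present/absent calls. A well is positive
#' when its amplicon melts at the positive-control Tm for that primerset
#' (within `tm_tolerance`) and its Ct is strictly below `ct_positive_max`.
#' The clinical runs use 45 cycles with a Ct < 44 rule; the temporal-stability
#' delta-Ct analysis uses 40 cycles with a housekeeper Ct cutoff of 35 —
#' both regimes are expressed through this configuration rather than
#' hard-coded.
#'
#' @param tm_tolerance maximal absolute deviation (degrees C) from the
#'   positive-control melt temperature; inclusive boundary. Default 1.5.
#' @param ct_positive_max a positive call requires Ct strictly below this
#'   cycle count. Default 44.
#' @param total_cycles cycles run on the instrument; also the censored Ct
#'   substituted in [specificity_delta_ct()]. Default 45.
#' @param replicate_rule replicate aggregation convention; only
#'   `"any_of_replicates"` (at least one positive replicate) is defined.
#' @param housekeeper_id id of the housekeeping microRNA used for delta-Ct
#'   normalisation. Default `"miR-423-3p"`.
#' @param housekeeper_ct_max housekeeper Ct above this renders a sample's
#'   delta-Ct row missing. Default 35.
#' @return An object of class `scoring_config`.
#' @export
#' @examples
#' scoring_config()
#' scoring_config(total_cycles = 40, housekeeper_ct_max = 35)
scoring_config <- function(tm_tolerance = 1.5,
                           ct_positive_max = 44,
                           total_cycles = 45L,
                           replicate_rule = "any_of_replicates",
                           housekeeper_id = "miR-423-3p",
                           housekeeper_ct_max = 35) {
  replicate_rule <- match.arg(replicate_rule, "any_of_replicates")
  stopifnot(is.numeric(tm_tolerance), length(tm_tolerance) == 1L, tm_tolerance > 0,
            is.numeric(ct_positive_max), length(ct_positive_max) == 1L,
            is.numeric(housekeeper_ct_max), length(housekeeper_ct_max) == 1L,
            is.numeric(total_cycles), length(total_cycles) == 1L)
  if (!(housekeeper_ct_max > 0 && housekeeper_ct_max <= ct_positive_max &&
        ct_positive_max <= total_cycles))
    stop("require 0 < housekeeper_ct_max <= ct_positive_max <= total_cycles")
  structure(list(tm_tolerance = tm_tolerance,
                 ct_positive_max = ct_positive_max,
                 total_cycles = as.integer(total_cycles),
                 replicate_rule = replicate_rule,
                 housekeeper_id = housekeeper_id,
                 housekeeper_ct_max = housekeeper_ct_max),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("qPCR qualitative scoring configuration\n")
  cat(sprintf("  positive call: |Tm - ref| <= %.2f C and Ct < %.1f (of %d cycles)\n",
              x$tm_tolerance, x$ct_positive_max, x$total_cycles))
  cat(sprintf("  replicate rule: %s\n", x$replicate_rule))
  cat(sprintf("  housekeeper: %s (Ct cutoff %.1f for delta-Ct)\n",
              x$housekeeper_id, x$housekeeper_ct_max))
  invisible(x)
}

#' Call a single qPCR well positive or negative
#'
#' A well is `"positive"` iff it shows a melt curve whose Tm lies within
#' `config$tm_tolerance` of the positive-control reference Tm for the
#' primerset, and its Ct is strictly below `config$ct_positive_max`.
#' Wells with no visible melt curve (`tm = NA`), no amplification
#' (`ct = NA`), or an off-temperature product are `"negative"`.
#'
#' @param ct numeric vector of Ct values; `NA` = no amplification.
#' @param tm numeric vector of melt temperatures (degrees C); `NA` = no
#'   visible melt curve.
#' @param reference_tm positive-control melt temperature for this primerset.
#'   A missing reference is an error, never a silent negative.
#' @param config a [scoring_config()].
#' @param mir_id id used in error messages when `reference_tm` is missing.
#' @return Character vector in `{"positive","negative"}`, one per well.
#' @export
#' @examples
#' call_well(36, 78.0, reference_tm = 78.5)            # positive
#' call_well(44, 78.5, reference_tm = 78.5)            # Ct boundary: negative
#' call_well(30, 80.2, reference_tm = 78.5)            # off-Tm: negative
call_well <- function(ct, tm, reference_tm, config = scoring_config(),
                      mir_id = "<unknown>") {
  stopifnot(inherits(config, "scoring_config"))
  if (length(reference_tm) != 1L || is.na(reference_tm))
    stop(sprintf("no positive-control reference Tm for primerset '%s'", mir_id))
  n <- max(length(ct), length(tm))
  ct <- rep_len(as.numeric(ct), n)
  tm <- rep_len(as.numeric(tm), n)
  pos <- !is.na(tm) & abs(tm - reference_tm) <= config$tm_tolerance &
    !is.na(ct) & ct < config$ct_positive_max
  ifelse(pos, "positive", "negative")
}

#' Aggregate replicate wells into one sample-level microRNA call
#'
#' Under the `"any_of_replicates"` convention, a (sample, microRNA) pair is
#' positive when at least one of its replicate wells is positive; the two-
#' replicate design of the assay is the common case but any replicate count
#' is accepted.
#'
#' @param wells data frame with columns `sample_id`, `mir_id`, `ct`, `tm`
#'   (and optionally `replicate`) for a single (sample, microRNA) pair.
#' @param reference_tm positive-control Tm for the primerset.
#' @param config a [scoring_config()].
#' @return One-row data frame with columns `sample_id`, `mir_id`, `call`
#'   (`"positive"`/`"negative"`), `n_replicates`, `n_positive_replicates`.
#' @export
call_sample <- function(wells, reference_tm, config = scoring_config()) {
  if (!is.data.frame(wells) || nrow(wells) == 0L)
    stop("call_sample() needs at least one well")
  if (length(unique(wells$sample_id)) != 1L || length(unique(wells$mir_id)) != 1L)
    stop("all wells must share one sample_id and one mir_id")
  calls <- call_well(wells$ct, wells$tm, reference_tm, config,
                     mir_id = wells$mir_id[1L])
  npos <- sum(calls == "positive")
  data.frame(sample_id = wells$sample_id[1L],
             mir_id = wells$mir_id[1L],
             call = if (npos >= 1L) "positive" else "negative",
             n_replicates = nrow(wells),
             n_positive_replicates = npos,
             stringsAsFactors = FALSE)
}

#' Score a full plate of wells into sample-level calls
#'
#' Groups wells by (sample, microRNA), looks up each primerset's positive-
#' control reference Tm and applies [call_sample()]. Wells flagged
#' `is_positive_control` are excluded from sample scoring.
#'
#' @param wells data frame of well records (`sample_id`, `mir_id`, `ct`,
#'   `tm`, optionally `replicate`, `is_positive_control`).
#' @param reference_tm data frame with columns `mir_id`, `reference_tm`.
#' @param config a [scoring_config()].
#' @return Data frame of sample-level calls, one row per (sample, microRNA).
#' @export
score_wells <- function(wells, reference_tm, config = scoring_config()) {
  stopifnot(is.data.frame(wells), is.data.frame(reference_tm))
  if (!all(c("mir_id", "reference_tm") %in% names(reference_tm)))
    stop("reference_tm needs columns mir_id, reference_tm")
  if (!is.null(wells$is_positive_control))
    wells <- wells[!isTRUE_vec(wells$is_positive_control), , drop = FALSE]
  if (nrow(wells) == 0L)
    return(data.frame(sample_id = character(), mir_id = character(),
                      call = character(), n_replicates = integer(),
                      n_positive_replicates = integer(),
                      stringsAsFactors = FALSE))
  ref <- stats::setNames(reference_tm$reference_tm,
                         normalize_mir_id(reference_tm$mir_id))
  key <- paste(wells$sample_id, wells$mir_id, sep = "\r")
  groups <- split(seq_len(nrow(wells)), factor(key, levels = unique(key)))
  out <- lapply(groups, function(idx) {
    w <- wells[idx, , drop = FALSE]
    mid <- normalize_mir_id(w$mir_id[1L])
    rtm <- if (mid %in% names(ref)) ref[[mid]] else NA_real_
    call_sample(w, rtm, config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == 1 | x == "TRUE" | x == "true")

#' Assemble sample-level calls into a binary call matrix
#'
#' @param calls data frame of calls as returned by [score_wells()] (columns
#'   `sample_id`, `mir_id`, `call`); duplicate (sample, microRNA) pairs are
#'   an error.
#' @param mir_panel ordered microRNA ids defining the columns; cells with no
#'   call are `NA`. Default [ebc_mir_panel()].
#' @return Integer matrix (samples x microRNAs) with values 1, 0 or `NA`;
#'   row order is sample order of first appearance, column order the panel
#'   order.
#' @export
#' @examples
#' calls <- data.frame(sample_id = c("s1", "s1", "s2"),
#'                     mir_id = c("miR-21", "miR-33b", "miR-21"),
#'                     call = c("positive", "negative", "positive"))
#' build_call_matrix(calls, mir_panel = c("miR-21", "miR-33b"))
build_call_matrix <- function(calls, mir_panel = ebc_mir_panel()) {
  stopifnot(is.data.frame(calls), length(mir_panel) >= 1L,
            !anyDuplicated(mir_panel))
  samples <- unique(as.character(calls$sample_id))
  m <- matrix(NA_integer_, nrow = length(samples), ncol = length(mir_panel),
              dimnames = list(samples, mir_panel))
  if (nrow(calls) > 0L) {
    mid <- normalize_mir_id(calls$mir_id)
    panel_norm <- normalize_mir_id(mir_panel)
    key <- paste(calls$sample_id, mid, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("duplicate (sample, microRNA) calls: ",
           paste(gsub("\r", " / ", dup), collapse = ", "))
    }
    keep <- mid %in% panel_norm
    if (any(keep)) {
      ri <- match(as.character(calls$sample_id)[keep], samples)
      ci <- match(mid[keep], panel_norm)
      m[cbind(ri, ci)] <- as.integer(calls$call[keep] == "positive")
    }
  }
  m
}

#' Housekeeper-normalised delta-Ct matrix
#'
#' For each sample and target microRNA, computes
#' `Ct(target) - Ct(housekeeper)` using the mean Ct over amplified
#' replicates. A cell is `NA` whenever the target did not amplify, or the
#' sample's housekeeper did not amplify or exceeded the configured
#' housekeeper Ct cutoff.
#'
#' @param wells data frame of well records including housekeeper wells.
#' @param targets target microRNA ids (columns of the result).
#' @param config a [scoring_config()]; its `housekeeper_id` and
#'   `housekeeper_ct_max` govern normalisation. Use
#'   `scoring_config(total_cycles = 40, housekeeper_ct_max = 35)` for the
#'   40-cycle temporal-stability regime.
#' @return Numeric matrix (samples x targets) of delta-Ct values with `NA`
#'   for missing cells.
#' @export
delta_ct_matrix <- function(wells, targets, config = scoring_config()) {
  stopifnot(is.data.frame(wells), length(targets) >= 1L)
  wells$mir_norm <- normalize_mir_id(wells$mir_id)
  hk <- normalize_mir_id(config$housekeeper_id)
  samples <- unique(as.character(wells$sample_id))
  targ_norm <- normalize_mir_id(targets)
  mean_ct <- function(x) { x <- x[!is.na(x)]; if (length(x)) mean(x) else NA_real_ }
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(targets),
              dimnames = list(samples, targets))
  for (s in samples) {
    ws <- wells[wells$sample_id == s, , drop = FALSE]
    hk_rows <- ws$mir_norm == hk
    if (!any(hk_rows)) {
      warning(sprintf("sample '%s' has no housekeeper (%s) wells; delta-Ct row left missing",
                      s, config$housekeeper_id))
      next
    }
    hk_ct <- mean_ct(ws$ct[hk_rows])
    if (is.na(hk_ct) || hk_ct > config$housekeeper_ct_max) next
    for (j in seq_along(targets)) {
      t_ct <- mean_ct(ws$ct[ws$mir_norm == targ_norm[j]])
      if (!is.na(t_ct)) m[s, j] <- t_ct - hk_ct
    }
  }
  m
}

#' Fold-sensitivity implied by a Ct difference
#'
#' Under perfect per-cycle doubling, a platform reaching threshold at
#' `ct_a` cycles versus `ct_b` on the same template implies a
#' `2^(ct_b - ct_a)`-fold sensitivity advantage of platform A; e.g. Ct 27
#' versus 31 is a 2^4 = 16-fold advantage.
#'
#' @param ct_a,ct_b Ct values of the two platforms on the same template.
#' @return The fold advantage of A over B (numeric).
#' @export
#' @examples
#' fold_sensitivity(27, 31)   # 16
fold_sensitivity <- function(ct_a, ct_b) {
  stopifnot(is.numeric(ct_a), is.numeric(ct_b), !is.na(ct_a), !is.na(ct_b))
  2 ^ (ct_b - ct_a)
}

#' PCR product length of a universally tagged microRNA amplicon
#'
#' The RT step integrates a universal tag so the product is the microRNA
#' template plus the tag: a 22-nt microRNA with the 40-bp tag yields a 62-bp
#' product (~60-63 bp across the 20-23 nt template range).
#'
#' @param mir_length_nt microRNA template length in nucleotides (> 0).
#' @param tag_length_bp universal tag length in base pairs (> 0).
#' @return Integer amplicon length in bp.
#' @export
#' @examples
#' amplicon_length(22, 40)   # 62
amplicon_length <- function(mir_length_nt, tag_length_bp) {
  stopifnot(is.numeric(mir_length_nt), is.numeric(tag_length_bp))
  if (any(is.na(mir_length_nt)) || any(is.na(tag_length_bp)) ||
      any(mir_length_nt <= 0) || any(tag_length_bp <= 0))
    stop("amplicon_length() requires positive template and tag lengths")
  as.integer(mir_length_nt + tag_length_bp)
}

#' MicroRNA-specificity delta-Ct of a primerset
#'
#' Specificity screen contrast: Ct without the poly(A) step (mRNA-derived
#' signal only) minus Ct with poly(A) (microRNA signal included). The larger
#' the difference, the more microRNA-specific the primerset. When the
#' no-poly(A) condition did not amplify its Ct is censored at `total_cycles`
#' and the result carries a `censored` attribute; the same substitution is
#' applied symmetrically if the poly(A) condition did not amplify.
#'
#' @param ct_with_polya Ct with the polyadenylation step, or `NA`.
#' @param ct_without_polya Ct without polyadenylation, or `NA`.
#' @param total_cycles cycles run; censored substitute for a non-amplified
#'   condition. Default 45.
#' @return Numeric delta-Ct with logical attribute `"censored"`.
#' @export
#' @examples
#' specificity_delta_ct(25, 33)       # 8, uncensored
#' specificity_delta_ct(25, NA)       # 20, censored at 45 cycles
specificity_delta_ct <- function(ct_with_polya, ct_without_polya,
                                 total_cycles = 45) {
  if (is.na(ct_with_polya) && is.na(ct_without_polya))
    stop("at least one condition must have amplified")
  censored <- is.na(ct_with_polya) || is.na(ct_without_polya)
  a <- if (is.na(ct_with_polya)) total_cycles else ct_with_polya
  b <- if (is.na(ct_without_polya)) total_cycles else ct_without_polya
  structure(b - a, censored = censored)
}
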