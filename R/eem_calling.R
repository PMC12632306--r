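#' Classify family variants into inherited / de novo / EEM
#'
#' Trio-based classification: variants present in a parent are inherited;
#' parent-absent variants clonal (VAF at or above `denovo_min_vaf`) in every
#' sibling are pre-zygotic de novo variants; remaining parent-absent
#' variants detected in at least one sibling are early embryonic mutations
#' (EEMs); anything else is unresolved. A variant detected in two or more
#' co-siblings is flagged shared.
#'
#' Note the intrinsic blind spot: an EEM that is fully clonal in every
#' sibling is indistinguishable from a de novo variant by VAF alone and is
#' labelled de novo.
#'
#' @param table a `variant_table` containing both parents and at least two
#'   sibling samples.
#' @param min_alt,min_vaf detection rule (defaults 3 reads and VAF 0.03).
#' @param denovo_min_vaf clonality threshold for the de novo call
#'   (default 0.3, the observed de novo VAF lower bound).
#' @param sibling_samples one sample per sibling used for detection
#'   (default: the `_buccal` sample of every non-parental individual, or the
#'   first sample per individual when no buccal exists).
#' @param parent_samples parental samples used when the table carries no
#'   parental presence flags.
#' @return data.frame of class `variant_calls`: variant, class, per-sibling
#'   detection flags (`det_<individual>`), `n_detected`, `shared`.
#' @export
classify_variants <- function(table, min_alt = 3, min_vaf = 0.03,
                              denovo_min_vaf = 0.3, sibling_samples = NULL,
                              parent_samples = NULL) {
  stopifnot(inherits(table, "variant_table"))
  meta <- sample_meta(table$samples)
  parent_ind <- c("mother", "father")
  if (is.null(sibling_samples)) {
    kids <- meta[!meta$individual %in% parent_ind, ]
    pick <- function(d) if ("buccal" %in% d$tissue)
      d$sample[d$tissue == "buccal"][1] else d$sample[1]
    sibling_samples <- vapply(split(kids, kids$individual), pick,
                              character(1))
  }
  if (length(sibling_samples) < 2)
    stop_arg("need >= 2 sibling samples for classification")
  v <- vaf_matrix(table, "vaf")
  a <- vaf_matrix(table, "alt")
  flags <- table$variants[, c("mother", "father")]
  parent_present <- rowSums(flags, na.rm = TRUE) > 0
  if (all(is.na(flags$mother) & is.na(flags$father))) {
    if (is.null(parent_samples))
      parent_samples <- meta$sample[meta$individual %in% parent_ind]
    if (length(parent_samples) < 2)
      stop_arg("parental samples (or presence flags) are required")
    pp <- a[, parent_samples, drop = FALSE] >= min_alt &
      v[, parent_samples, drop = FALSE] >= min_vaf
    parent_present <- rowSums(pp, na.rm = TRUE) > 0
  }
  sv <- v[, sibling_samples, drop = FALSE]
  sa <- a[, sibling_samples, drop = FALSE]
  det <- !is.na(sv) & sa >= min_alt & sv >= min_vaf
  clonal_all <- rowSums(!is.na(sv) & sv >= denovo_min_vaf) ==
    length(sibling_samples)
  n_det <- rowSums(det)
  class <- ifelse(parent_present, "inherited",
                  ifelse(clonal_all, "de_novo",
                         ifelse(n_det >= 1, "eem", "unresolved")))
  out <- data.frame(variant = as.character(table$variants$variant),
                    class = class, stringsAsFactors = FALSE)
  sibs <- names(sibling_samples) %||% sibling_samples
  for (i in seq_along(sibling_samples))
    out[[paste0("det_", sibs[i])]] <- det[, i]
  out$n_detected <- n_det
  out$shared <- n_det >= 2
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Per-pair sharing summary of variant calls
#'
#' @param calls a `variant_calls` data.frame from [classify_variants()].
#' @return list: counts of de novo and EEM calls, the shared fraction of
#'   each class (shared detections / detected calls of the class), and a
#'   `clonal_shared_frac` zygosity score — among variants clonal in at least
#'   one sibling, the fraction clonal in all (near 1 for one zygote, near 0
#'   for two).
#' @export
pair_summary <- function(calls) {
  stopifnot(inherits(calls, "variant_calls"))
  frac <- function(cls) {
    k <- calls$class == cls & calls$n_detected >= 1
    if (!any(k)) return(NA_real_)
    mean(calls$shared[k])
  }
  n_dn <- sum(calls$class == "de_novo")
  n_eem <- sum(calls$class == "eem")
  # clonality-based zygosity score: de_novo calls are clonal-in-all by
  # definition; clonal-in-one-only variants surface as high-VAF EEM calls
  det_cols <- grep("^det_", names(calls))
  list(n_denovo = n_dn, n_eem = n_eem,
       shared_frac_denovo = frac("de_novo"),
       shared_frac_eem = frac("eem"),
       n_shared_eem = sum(calls$class == "eem" & calls$shared),
       n_siblings = length(det_cols))
}

#' Zygosity check from clonal sharing
#'
#' Fraction of somatically clonal variants (VAF at or above `clonal_min_vaf`
#' in at least one sibling) that are clonal in all siblings; approximately 1
#' for a shared zygote and approximately 0 for dizygotic pairs.
#'
#' @param table a `variant_table`.
#' @param sibling_samples detection samples (see [classify_variants()]).
#' @param clonal_min_vaf clonality threshold (default 0.3).
#' @param exclude_inherited drop variants flagged present in a parent.
#' @return fraction in `[0, 1]` (NA when no clonal variants).
#' @export
clonal_shared_fraction <- function(table, sibling_samples = NULL,
                                   clonal_min_vaf = 0.3,
                                   exclude_inherited = TRUE) {
  meta <- sample_meta(table$samples)
  if (is.null(sibling_samples)) {
    kids <- meta[!meta$individual %in% c("mother", "father"), ]
    sibling_samples <- vapply(split(kids, kids$individual), function(d)
      if ("buccal" %in% d$tissue) d$sample[d$tissue == "buccal"][1]
      else d$sample[1], character(1))
  }
  v <- vaf_matrix(table)[, sibling_samples, drop = FALSE]
  keep <- rep(TRUE, nrow(v))
  if (exclude_inherited) {
    fl <- table$variants[, c("mother", "father")]
    keep <- !(rowSums(fl, na.rm = TRUE) > 0)
  }
  clonal <- !is.na(v) & v >= clonal_min_vaf
  any_cl <- keep & rowSums(clonal) >= 1
  if (!any(any_cl)) return(NA_real_)
  mean(rowSums(clonal[any_cl, , drop = FALSE]) == ncol(v))
}
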