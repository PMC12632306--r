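#' Variant allele fraction from read counts
#'
#' @param alt alt read count(s).
#' @param depth total read depth(s).
#' @return `alt / depth`, or `NA` where `depth` is 0 (missing is distinct
#'   from a VAF of 0 throughout the package).
#' @examples
#' vaf_from_counts(30, 60)   # 0.5
#' vaf_from_counts(5, 0)     # NA
#' @export
vaf_from_counts <- function(alt, depth) {
  if (any(alt < 0) || any(depth < 0)) stop_arg("counts must be non-negative")
  if (any(alt > depth & depth > 0)) stop_arg("alt count exceeds depth")
  ifelse(depth > 0, alt / depth, NA_real_)
}

#' Build a variant table
#'
#' The central bulk-sequencing container: one row per (family, variant,
#' sample) with read depth, alt count and VAF, plus per-variant metadata
#' (coordinates and parental presence flags).
#'
#' @param data data.frame with columns family, variant, sample, depth, alt
#'   (vaf is recomputed).
#' @param variants optional per-variant data.frame with columns variant and
#'   any of chrom, pos, ref, alt, mother, father (logical presence flags).
#' @param samples sample order (default: order of first appearance).
#' @return object of class `variant_table`.
#' @export
variant_table <- function(data, variants = NULL, samples = NULL) {
  need <- c("family", "variant", "sample", "depth", "alt")
  if (!all(need %in% names(data)))
    stop_arg("data must have columns %s", paste(need, collapse = ", "))
  if (any(data$alt > data$depth))
    stop_arg("alt count exceeds depth at row %d",
             which(data$alt > data$depth)[1])
  data$vaf <- vaf_from_counts(data$alt, data$depth)
  samples <- samples %||% unique(as.character(data$sample))
  vids <- unique(as.character(data$variant))
  if (length(vids) == 0) {
    variants <- data.frame(variant = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), mother = logical(0),
                           father = logical(0), stringsAsFactors = FALSE)
  } else if (is.null(variants)) {
    variants <- data.frame(variant = vids, chrom = "chr1",
                           pos = seq_along(vids), ref = "N", alt = "N",
                           mother = NA, father = NA,
                           stringsAsFactors = FALSE)
  } else {
    for (col in c("chrom", "pos", "ref", "alt"))
      if (is.null(variants[[col]]))
        variants[[col]] <- switch(col, chrom = "chr1",
                                  pos = seq_len(nrow(variants)), "N")
    for (col in c("mother", "father"))
      if (is.null(variants[[col]])) variants[[col]] <- NA
    variants <- variants[match(vids, as.character(variants$variant)), ]
  }
  rownames(variants) <- NULL
  data <- data[order(match(as.character(data$variant), vids),
                     match(as.character(data$sample), samples)), ]
  rownames(data) <- NULL
  structure(list(data = data, variants = variants, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples (%s)\n",
              nrow(x$variants), length(x$samples),
              paste(unique(x$data$family), collapse = ", ")))
  invisible(x)
}

#' Extract a VAF (or depth/alt) matrix from a variant table
#'
#' @param table a `variant_table`.
#' @param field one of `"vaf"`, `"depth"`, `"alt"`.
#' @return matrix variants x samples.
#' @export
vaf_matrix <- function(table, field = "vaf") {
  stopifnot(inherits(table, "variant_table"))
  m <- matrix(NA_real_, nrow(table$variants), length(table$samples),
              dimnames = list(as.character(table$variants$variant),
                              table$samples))
  i <- cbind(match(as.character(table$data$variant), rownames(m)),
             match(as.character(table$data$sample), table$samples))
  m[i] <- table$data[[field]]
  m
}

# individual/tissue parsed from sample names of the form <individual>_<tissue>;
# tissue labels may themselves contain underscores (cord_blood, ...)
sample_meta <- function(samples) {
  tissues <- c("cord_blood", "umbilical_cord", "placenta_patch", "buccal",
               "pbmc")
  parse1 <- function(s) {
    for (t in tissues) {
      suf <- paste0("_", t)
      if (endsWith(s, suf))
        return(c(substr(s, 1, nchar(s) - nchar(suf)), t))
    }
    c(sub("_[^_]*$", "", s), sub("^.*_", "", s))
  }
  parts <- vapply(samples, parse1, character(2))
  data.frame(sample = samples, individual = parts[1, ],
             tissue = parts[2, ], stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a variant table
#'
#' TSV output uses the fixed header `family variant sample depth alt vaf`.
#' VCF output is v4.2, one family per file, with per-sample `DP:AD` FORMAT
#' fields, parental presence flags in INFO (`MP`/`FP`) and the family id in
#' a `##family=` header line; records are sorted by chromosome and position
#' and sample columns keep the table's order. Parental flags do not survive
#' the bare TSV (they are re-derived from parent sample rows on read).
#'
#' @param table a `variant_table`.
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(table, "variant_table"))
  format <- match.arg(format)
  fams <- unique(as.character(table$data$family))
  if (length(fams) && any(grepl("[^ -~]", fams)))
    stop_arg("family ids must be ASCII")
  if (format == "tsv") {
    d <- table$data
    d$vaf <- ifelse(is.na(d$vaf), "NA", format(d$vaf, digits = 15))
    utils::write.table(d[, c("family", "variant", "sample", "depth",
                             "alt", "vaf")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (length(fams) > 1) stop_arg("VCF output is one family per file")
  v <- table$variants
  dp <- vaf_matrix(table, "depth")
  ad <- vaf_matrix(table, "alt")
  ord <- order(as.integer(sub("^chr", "", v$chrom)), v$pos)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##family=%s", if (length(fams)) fams else "NA"),
           sprintf("##contig=<ID=chr%d,length=125000000>", 1:24),
           "##INFO=<ID=MP,Number=1,Type=Integer,Description=\"Present in mother (1/0)\">",
           "##INFO=<ID=FP,Number=1,Type=Integer,Description=\"Present in father (1/0)\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", table$samples), collapse = "\t"))
  flag <- function(x) ifelse(is.na(x), ".", as.integer(as.logical(x)))
  info <- paste0("MP=", flag(v$mother), ";FP=", flag(v$father))
  recs <- vapply(ord, function(i) {
    gt <- vapply(table$samples, function(s) {
      d <- dp[i, s]; a <- ad[i, s]
      if (is.na(d)) "." else sprintf("%d:%d,%d", d, max(d - a, 0), a)
    }, character(1))
    paste(c(v$chrom[i], v$pos[i], as.character(v$variant[i]), v$ref[i],
            v$alt[i], ".", "PASS", info[i], "DP:AD", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a variant table
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (VCF must carry DP and AD per sample).
#' @return a `variant_table`. Reading then writing reproduces the file's
#'   content (canonical ordering).
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  if (format == "tsv") {
    need <- c("family", "variant", "sample", "depth", "alt", "vaf")
    hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, need))
      stop_arg("malformed TSV header: expected '%s'",
               paste(need, collapse = " "))
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(family = "character",
                                          variant = "character",
                                          sample = "character"))
    bad <- which(d$alt > d$depth | d$alt < 0 | d$depth < 0)
    if (length(bad))
      stop_arg("invalid counts at line %d of %s", bad[1] + 1L, path)
    return(variant_table(d[, c("family", "variant", "sample", "depth",
                               "alt")]))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, "FORMAT", drop = TRUE]
  if (!all(grepl("DP", fmt)) || !all(grepl("AD", fmt)))
    stop_arg("VCF must carry DP and AD FORMAT fields: %s", path)
  fam <- sub("^##family=", "", grep("^##family=", vcf@meta, value = TRUE))
  if (!length(fam)) fam <- sub("\\.vcf$", "", basename(path))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  altmat <- suppressWarnings(
    matrix(as.numeric(sub("^[^,]*,", "", ad)), nrow = nrow(ad),
           dimnames = dimnames(ad)))
  info_flag <- function(key) {
    m <- regmatches(fix$INFO, regexpr(sprintf("%s=[^;]+", key), fix$INFO))
    val <- rep(NA_character_, nrow(fix))
    val[grepl(sprintf("%s=", key), fix$INFO)] <- sub("^.*=", "", m)
    ifelse(val %in% c("0", "1"), val == "1", NA)
  }
  long <- data.frame(
    family = fam,
    variant = rep(fix$ID, times = length(samples)),
    sample = rep(samples, each = nrow(fix)),
    depth = as.vector(ifelse(is.na(dp), 0, dp)),
    alt = as.vector(ifelse(is.na(altmat), 0, altmat)),
    stringsAsFactors = FALSE
  )
  variants <- data.frame(variant = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, mother = info_flag("MP"),
                         father = info_flag("FP"), stringsAsFactors = FALSE)
  variant_table(long, variants, samples)
}
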