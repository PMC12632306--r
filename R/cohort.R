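#' Cohort configuration
#'
#' Study conditions for the synthetic cohort: 8 MCMA + 7 MCDA + 7 DCDA
#' monozygotic pairs, 1 dichorionic triamniotic monozygotic triplet and 6
#' dizygotic pairs. Clonal-category frequencies per membrane type default to
#' the observed cohort proportions (monoamniotic twins almost exclusively
#' full-identical; diamniotic twins dominated by sub- and para-identical),
#' and monochorionic cord-blood mixing draws the major contributor uniformly
#' from 56--83%.
#'
#' @param n_mcma,n_mcda,n_dcda numbers of MZ pairs per membrane type.
#' @param n_triplet number of MZ triplets (DCTA).
#' @param n_dz number of dizygotic control pairs.
#' @param params a [sim_params()].
#' @param tissues tissues sampled per individual.
#' @param progenitors named list of bottleneck sizes per tissue.
#' @param mode_probs named list of category probabilities per membrane type.
#' @param split_generations named list: twinning generation per mode.
#' @param f_range monochorionic major-contributor range for blood mixing.
#' @param n_inherited inherited (parental) variants per family, used to
#'   exercise trio subtraction.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_mcma = 8, n_mcda = 7, n_dcda = 7, n_triplet = 1,
                          n_dz = 6, params = sim_params(),
                          tissues = c("buccal", "cord_blood"),
                          progenitors = list(buccal = 128, cord_blood = 128,
                                             placenta_patch = 8,
                                             umbilical_cord = 32,
                                             pbmc = 128),
                          mode_probs = list(
                            MCMA = c(para = 0, sub = 1 / 8, full = 7 / 8),
                            MCDA = c(para = 3 / 14, sub = 9 / 14,
                                     full = 2 / 14),
                            DCDA = c(para = 3 / 14, sub = 9 / 14,
                                     full = 2 / 14)),
                          split_generations = list(para = 1, sub = 6,
                                                   full = 7),
                          f_range = c(0.56, 0.83), n_inherited = 30) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Load a cohort configuration from YAML
#'
#' Scalar fields override [cohort_config()] defaults; `params` entries
#' override [sim_params()] defaults.
#'
#' @param path YAML file.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  pars <- do.call(sim_params, y$params %||% list())
  y$params <- NULL
  known <- names(formals(cohort_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_arg("unknown config fields: %s",
                            paste(bad, collapse = ", "))
  if (!is.null(y$mode_probs)) y$mode_probs <- lapply(y$mode_probs, unlist)
  do.call(cohort_config, c(y, list(params = pars)))
}

# sequence a set of true VAFs at a given mean depth (shared noise model)
.seq_counts <- function(true_vaf, mean_depth, e) {
  depth <- stats::rpois(length(true_vaf), mean_depth)
  p <- true_vaf * (1 - e) + (1 - true_vaf) * e / 3
  alt <- stats::rbinom(length(true_vaf), depth, p)
  list(depth = depth, alt = alt)
}

# build one family's bulk variant table from per-sample true VAF vectors
.family_table <- function(family_id, variants, true_vafs, mean_depth, e) {
  samples <- names(true_vafs)
  rows <- lapply(samples, function(s) {
    cnt <- .seq_counts(true_vafs[[s]], mean_depth, e)
    data.frame(family = family_id, variant = variants$variant, sample = s,
               depth = cnt$depth, alt = cnt$alt, stringsAsFactors = FALSE)
  })
  variant_table(do.call(rbind, rows), variants, samples)
}

# inherited-variant scaffold: presence flags and transmission per individual
.inherited_variants <- function(family_id, n, individuals, mz_share,
                                genome_size) {
  if (n == 0) return(NULL)
  pos <- sample(genome_size, n)
  parent <- sample(c("mother", "father"), n, replace = TRUE)
  trans <- matrix(stats::runif(n * length(individuals)) < 0.5, nrow = n,
                  dimnames = list(NULL, individuals))
  if (mz_share && length(individuals) > 1)  # one zygote: one transmission
    for (j in seq_along(individuals)[-1]) trans[, j] <- trans[, 1]
  list(meta = data.frame(
         variant = paste0(family_id, "_i", seq_len(n)),
         chrom = paste0("chr", 1 + (pos - 1) %/% 125e6),
         pos = as.integer((pos - 1) %% 125e6 + 1),
         ref = "A", alt = "G",
         mother = parent == "mother", father = parent == "father",
         stringsAsFactors = FALSE),
       trans = trans, parent = parent)
}

#' Simulate one twin (or triplet) family
#'
#' @param family_id family label.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param membrane `"MCMA"`, `"MCDA"`, `"DCDA"` or `"DCTA"` (triplet).
#' @param mode clonal category to simulate for MZ pairs (drawn from
#'   `config$mode_probs` when `NULL`).
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return a `twin_family` list: trees, partition, tissue samples, the
#'   60x whole-genome `variant_table` (children + both parents) and a
#'   `truth` record.
#' @export
simulate_family <- function(family_id, zygosity, membrane, mode = NULL,
                            config = cohort_config(), seed = NULL) {
  pars <- config$params
  with_seed(seed, {
    triplet <- identical(membrane, "DCTA")
    if (zygosity == "MZ") {
      tree <- simulate_lineage(pars)
      if (triplet) {
        part <- simulate_triplet(tree)
        twins <- c("T1", "T2", "T3")
      } else {
        mode <- mode %||% sample(names(config$mode_probs[[membrane]]), 1,
                                 prob = config$mode_probs[[membrane]])
        part <- apply_twinning(tree, mode,
                               config$split_generations[[mode]])
        twins <- c("twin1", "twin2")
      }
      trees <- stats::setNames(rep(list(tree), length(twins)), twins)
    } else {
      twins <- c("twin1", "twin2")
      trees <- stats::setNames(lapply(twins, function(t)
        simulate_lineage(pars)), twins)
      part <- NULL
    }
    individuals <- paste0("T", seq_along(twins))
    # tissue founding per individual
    samp <- list()
    for (i in seq_along(twins)) {
      tr <- trees[[i]]
      p <- if (zygosity == "MZ") part else list(founders = list(self = 1L))
      tw <- if (zygosity == "MZ") twins[i] else "self"
      for (tis in config$tissues)
        samp[[paste(individuals[i], tis, sep = "_")]] <-
          sample_tissue(tr, p, tw, tis, config$progenitors[[tis]],
                        individual = individuals[i])
    }
    # monochorionic blood mixing
    f <- NA_real_
    mono <- membrane %in% c("MCMA", "MCDA")
    if (mono && "cord_blood" %in% config$tissues && !triplet) {
      f <- stats::runif(1, config$f_range[1], config$f_range[2])
      if (stats::runif(1) < 0.5) f <- 1 - f   # random major twin
      mixed <- mix_cord_blood(samp[["T1_cord_blood"]],
                              samp[["T2_cord_blood"]], f, "monochorionic")
      samp[["T1_cord_blood"]] <- mixed[[1]]
      samp[["T2_cord_blood"]] <- mixed[[2]]
    }
    # variant metadata: somatic catalogs (per zygote) + inherited variants
    cats <- lapply(seq_along(trees), function(i) {
      cat <- trees[[i]]$catalog
      if (zygosity == "DZ" || i == 1) cat else cat[0, ]
    })
    vmeta <- do.call(rbind, lapply(seq_along(cats), function(i) {
      cat <- cats[[i]]
      if (!nrow(cat)) return(NULL)
      data.frame(variant = paste0(family_id, "_z", i, "m", cat$mut_id),
                 chrom = cat$chrom, pos = cat$pos, ref = cat$ref,
                 alt = cat$alt, mother = FALSE, father = FALSE,
                 origin_class = cat$origin_class, zygote = i,
                 mut_id = cat$mut_id, stringsAsFactors = FALSE)
    }))
    inh <- .inherited_variants(family_id, config$n_inherited, individuals,
                               zygosity == "MZ", pars$genome_size)
    # per-sample true VAFs over (somatic union + inherited)
    true_vafs <- lapply(samp, function(s) {
      ind <- match(s$individual, individuals)
      zyg <- if (zygosity == "DZ") ind else 1L
      somatic <- ifelse(vmeta$zygote == zyg,
                        s$true_vaf[vmeta$mut_id], 0)
      inherited <- if (is.null(inh)) numeric(0) else
        ifelse(inh$trans[, individuals[ind]], 0.5, 0)
      c(somatic, inherited)
    })
    true_vafs$mother_pbmc <- c(rep(0, nrow(vmeta)),
                               if (is.null(inh)) numeric(0) else
                                 ifelse(inh$parent == "mother", 0.5, 0))
    true_vafs$father_pbmc <- c(rep(0, nrow(vmeta)),
                               if (is.null(inh)) numeric(0) else
                                 ifelse(inh$parent == "father", 0.5, 0))
    variants <- rbind(
      data.frame(vmeta[, c("variant", "chrom", "pos", "ref", "alt",
                           "mother", "father")],
                 stringsAsFactors = FALSE),
      if (!is.null(inh)) inh$meta)
    table <- .family_table(family_id, variants, true_vafs,
                           pars$wgs_depth, pars$seq_error)
    truth_class <- c(vmeta$origin_class,
                     if (!is.null(inh)) rep("inherited", nrow(inh$meta)))
    truth <- list(family = family_id, zygosity = zygosity,
                  membrane = membrane, mode = if (triplet) "triplet" else
                    (mode %||% NA_character_),
                  true_a = if (inherits(part, "twin_partition"))
                    part$true_a else NA_real_,
                  true_b = if (inherits(part, "twin_partition"))
                    part$true_b else NA_real_,
                  split_generation = if (inherits(part, "twin_partition"))
                    part$split_generation else NA_integer_,
                  f = f,
                  variant_class = stats::setNames(truth_class,
                                                  variants$variant),
                  topology = if (triplet) part$true_topology else NA)
    structure(list(family_id = family_id, zygosity = zygosity,
                   membrane = membrane, individuals = individuals,
                   trees = trees, partition = part, samples = samp,
                   table = table, vmeta = vmeta, truth = truth,
                   params = pars),
              class = "twin_family")
  })
}

#' Deep-targeted resequencing of candidate variants
#'
#' Re-sequences the named variants in every (non-parent) sample of a family
#' at the targeted mean depth, mirroring validation of WGS candidates by
#' deep amplicon sequencing.
#'
#' @param family a `twin_family`.
#' @param variant_ids variants to re-sequence.
#' @param seed optional integer seed.
#' @return a `variant_table` at targeted depth.
#' @export
targeted_resequence <- function(family, variant_ids, seed = NULL) {
  with_seed(seed, {
    tab <- family$table
    idx <- match(variant_ids, as.character(tab$variants$variant))
    if (anyNA(idx)) stop_arg("unknown variant ids")
    child_samples <- setdiff(tab$samples, c("mother_pbmc", "father_pbmc"))
    tv <- .true_vaf_matrix(family)[idx, , drop = FALSE]
    rows <- lapply(child_samples, function(s) {
      cnt <- .seq_counts(tv[, s], family$params$targeted_depth,
                         family$params$seq_error)
      data.frame(family = family$family_id, variant = variant_ids,
                 sample = s, depth = cnt$depth, alt = cnt$alt,
                 stringsAsFactors = FALSE)
    })
    variant_table(do.call(rbind, rows),
                  tab$variants[idx, , drop = FALSE], child_samples)
  })
}

# true VAF matrix (variants x child samples) recomputed from stored samples
.true_vaf_matrix <- function(family) {
  vmeta <- family$vmeta
  individuals <- family$individuals
  out <- sapply(family$samples, function(s) {
    ind <- match(s$individual, individuals)
    zyg <- if (family$zygosity == "DZ") ind else 1L
    somatic <- ifelse(vmeta$zygote == zyg, s$true_vaf[vmeta$mut_id], 0)
    c(somatic, rep(NA_real_,
                   nrow(family$table$variants) - nrow(vmeta)))
  })
  # inherited truth is not needed downstream; carry observed table VAFs
  inh_rows <- setdiff(seq_len(nrow(family$table$variants)),
                      seq_len(nrow(vmeta)))
  if (length(inh_rows)) {
    vm <- vaf_matrix(family$table)
    out[inh_rows, ] <- vm[inh_rows, colnames(out)]
  }
  rownames(out) <- as.character(family$table$variants$variant)
  out
}

#' Simulate the full twin cohort
#'
#' @param config a [cohort_config()] (or path to a YAML config).
#' @param seed integer seed; every family derives its own stream from it.
#' @return object of class `twin_cohort`: list of `twin_family` objects,
#'   a metadata data.frame and the per-family truth records.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_mcma = 1, n_mcda = 0, n_dcda = 1,
#'                                      n_triplet = 0, n_dz = 1), seed = 1)
#' coh$metadata
#' }
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  if (is.character(config)) config <- read_cohort_config(config)
  plan <- data.frame(
    zygosity = rep(c("MZ", "MZ", "MZ", "MZ", "DZ"),
                   c(config$n_mcma, config$n_mcda, config$n_dcda,
                     config$n_triplet, config$n_dz)),
    membrane = rep(c("MCMA", "MCDA", "DCDA", "DCTA", "DCDA"),
                   c(config$n_mcma, config$n_mcda, config$n_dcda,
                     config$n_triplet, config$n_dz)),
    stringsAsFactors = FALSE)
  plan$family <- sprintf("F%02d", seq_len(nrow(plan)))
  families <- lapply(seq_len(nrow(plan)), function(i)
    simulate_family(plan$family[i], plan$zygosity[i], plan$membrane[i],
                    config = config, seed = derive_seed(seed, i)))
  names(families) <- plan$family
  truth <- lapply(families, `[[`, "truth")
  meta <- data.frame(family = plan$family, zygosity = plan$zygosity,
                     membrane = plan$membrane,
                     mode = vapply(truth, function(t) t$mode, character(1)),
                     true_a = vapply(truth, function(t) t$true_a, double(1)),
                     true_b = vapply(truth, function(t) t$true_b, double(1)),
                     f = vapply(truth, function(t) t$f, double(1)),
                     stringsAsFactors = FALSE)
  structure(list(families = families, metadata = meta, truth = truth,
                 config = config, seed = seed),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("twin_cohort: %d families (%s)\n", nrow(x$metadata),
              paste(sprintf("%s=%d", names(table(x$metadata$membrane)),
                            table(x$metadata$membrane)), collapse = ", ")))
  invisible(x)
}
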