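# End-to-end orchestration: validate -> align (k parameterisations) ->
# consensus -> strip -> ML + bootstrap (with NJ and parsimony
# cross-checks) -> root -> group -> name -> conservation matrix -> core
# set.  Every stage logs one structured line and lands its outputs in the
# manifest; identical config + seeds give byte-identical outputs.

#' Pipeline configuration
#'
#' @param catalog,registry,fasta input file paths (`fasta` may be NULL in
#'   catalog-only mode).
#' @param out_dir output directory.
#' @param mode `"full"` (sequence stages + nomenclature) or
#'   `"catalog_only"` (nomenclature/core-set stages from declared
#'   annotations, optionally with a provided Newick tree).
#' @param tree optional Newick file with supports (used in catalog-only
#'   mode).
#' @param msa_params list of gap-penalty parameterisations (each
#'   `list(open =, extend =)`); at least two, feeding the consensus merge.
#' @param min_run low-complexity masking threshold (residues).
#' @param max_gap_frac gap-column threshold for [strip_gap_columns()].
#' @param bootstrap_replicates nonparametric bootstrap replicates
#'   (default 100).
#' @param nomenclature a [nomenclature_config()].
#' @param validation a [validation_config()].
#' @param refine_after_exclusion re-infer the tree after removing distant
#'   relatives (mirrors the two-pass analysis; default TRUE).
#' @param model a [rate_model()].
#' @param seed integer master seed.
#' @param verbose print one log line per stage.
#' @export
pipeline_config <- function(catalog, registry, fasta = NULL,
                            out_dir = tempfile("degphylo_run_"),
                            mode = c("full", "catalog_only"), tree = NULL,
                            msa_params = list(list(open = 10, extend = 1),
                                              list(open = 5, extend = 2)),
                            min_run = 10L, max_gap_frac = 0,
                            bootstrap_replicates = 100L,
                            nomenclature = nomenclature_config(),
                            validation = validation_config(),
                            refine_after_exclusion = TRUE,
                            model = wag_model(), seed = 1L,
                            verbose = TRUE) {
  mode <- match.arg(mode)
  stopifnot(bootstrap_replicates >= 1L, length(msa_params) >= 1L)
  cfg <- as.list(environment())
  class(cfg) <- "deg_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' `msa_params` is a list of `open`/`extend` pairs.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- intersect(names(y), names(formals(pipeline_config)))
  do.call(pipeline_config, y[known])
}

#' Run the full nomenclature pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the key results (`validation`, `msa`,
#'   `tree`, `groups`, `names`, `matrix`, `core_set`, `manifest`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "deg_pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character())
  log_line <- function(stage, ...) {
    if (config$verbose)
      message(sprintf("[%s] %s", stage, paste0(...)))
  }
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file))))
    file
  }
  out <- function(name) file.path(config$out_dir, name)

  if (!file.exists(config$catalog))
    stop("catalog file not found: ", config$catalog)
  if (!file.exists(config$registry))
    stop("registry file not found: ", config$registry)
  catalog <- load_catalog(config$catalog, config$registry)
  log_line("catalog", nrow(catalog$records), " records, ",
           nrow(catalog$registry), " species")
  res <- list(catalog = catalog)

  if (config$mode == "full") {
    if (is.null(config$fasta) || !file.exists(config$fasta %||% ""))
      stop("full mode needs an existing FASTA file")
    seqs <- load_fasta(config$fasta)
    disc <- cross_validate(catalog, seqs)
    if (nrow(disc)) log_line("cross-validate", nrow(disc), " discrepancies")

    v <- validate_catalog(catalog, seqs, config = config$validation)
    write_tsv(v, emit("validate", out("validation.tsv")))
    log_line("validate", sum(v$eligible), "/", nrow(v), " eligible")
    eligible <- intersect(v$id[v$eligible], names(seqs))
    if (length(eligible) < 3L)
      stop("fewer than 3 eligible sequences; cannot infer a tree")

    masked <- vapply(seqs[eligible], mask_low_complexity,
                     "", min_run = config$min_run)
    m <- blosum62_matrix()
    alns <- lapply(seq_along(config$msa_params), function(k) {
      p <- config$msa_params[[k]]
      g <- gap_penalties(p$open, p$extend)
      a <- progressive_align(masked, m = m, g = g)
      write_alignment(a, emit(paste0("align_", k),
                              out(sprintf("alignment_run%d.fasta", k))))
      a
    })
    log_line("align", length(alns), " runs over ", length(masked),
             " sequences")
    cons <- consensus_merge(alns)
    write_alignment(cons, emit("consensus", out("consensus.fasta")))
    stripped <- strip_gap_columns(cons, config$max_gap_frac)
    write_alignment(stripped, emit("strip", out("stripped.fasta")))
    write_tsv(data.frame(kept_column = attr(stripped, "kept_columns")),
              emit("strip", out("column_map.tsv")))
    log_line("consensus", ncol(cons), " agreed columns, ",
             ncol(stripped), " after gap stripping")
    res$msa <- stripped

    infer <- function(a, tag) {
      bt <- bootstrap_supports(a, config$model,
                               bootstrap_config(config$bootstrap_replicates,
                                                config$seed))
      write_newick(bt, emit(tag, out(paste0(tag, ".nwk"))))
      bt
    }
    ml <- infer(stripped, "ml_tree")
    log_line("ml", "loglik ", round(attr(ml, "loglik") %||% NA, 2))
    # cross-checks: NJ topology and parsimony scores, RF distances logged
    njt <- neighbor_joining(pairwise_distances(stripped))
    write_newick(njt, emit("nj_tree", out("nj_tree.nwk")))
    rf_nj <- rf_distance(ml, njt)
    pars_ml <- fitch_parsimony_score(ml, stripped)
    pars_nj <- fitch_parsimony_score(njt, stripped)
    log_line("crosscheck", "RF(ml, nj) = ", rf_nj,
             "; parsimony ml/nj = ", pars_ml, "/", pars_nj)

    outgroup_sp <- catalog$registry$code[catalog$registry$is_outgroup]
    og <- catalog$records$id[catalog$records$species %in% outgroup_sp]
    og <- intersect(og, ml$tip.label)
    rooted <- if (length(og)) root_with_outgroup(ml, og)
              else apply_split_labels(phangorn::midpoint(ml),
                                      label_splits(ml))
    if (!length(og)) log_line("root", "no outgroup present; midpoint root")

    excl <- exclude_distant_relatives(rooted, catalog, config$nomenclature)
    write_tsv(excl$excluded, emit("exclude", out("excluded.tsv")))
    if (nrow(excl$excluded)) {
      log_line("exclude", nrow(excl$excluded), " distant relatives/flagged")
      keep <- union(excl$retained, og)
      if (config$refine_after_exclusion &&
          length(setdiff(keep, og)) >= 3L) {
        a2 <- structure(unclass(stripped)[keep, , drop = FALSE],
                        class = "deg_msa")
        a2 <- strip_gap_columns(a2, config$max_gap_frac)
        ml <- infer(a2, "ml_tree_refined")
        rooted <- if (length(og)) root_with_outgroup(ml, og)
                  else apply_split_labels(phangorn::midpoint(ml),
                                          label_splits(ml))
        res$msa <- a2
      }
    }
    write_newick(rooted, emit("root", out("rooted_tree.nwk")))
    res$tree <- rooted

    groups <- assign_ortholog_groups(rooted, catalog, config$nomenclature)
    nm <- propose_names(groups, catalog, config$nomenclature)
  } else {
    if (!is.null(config$tree)) {
      tr <- read_newick(file = config$tree)
      outgroup_sp <- catalog$registry$code[catalog$registry$is_outgroup]
      og <- intersect(catalog$records$id[catalog$records$species %in%
                                           outgroup_sp], tr$tip.label)
      if (length(og)) tr <- root_with_outgroup(tr, og)
      res$tree <- tr
      groups <- assign_ortholog_groups(tr, catalog, config$nomenclature)
      nm <- propose_names(groups, catalog, config$nomenclature)
    } else {
      groups <- catalog_groups(catalog, config$nomenclature)
      nm <- setNames(catalog$records$proposed_name,
                     catalog$records$id)[groups$assignment$id]
      log_line("groups", "catalog-only mode: declared groups")
    }
  }

  asn <- groups$assignment
  asn$proposed_name <- nm[asn$id]
  write_tsv(asn, emit("groups", out("groups.tsv")))
  log_line("groups", length(unique(asn$group)), " ortholog groups")
  res$groups <- groups
  res$names <- nm

  conc <- architecture_concordance(groups, catalog)
  write_tsv(conc, emit("concordance", out("concordance.tsv")))

  cm <- build_conservation_matrix(groups, catalog$registry, names = nm)
  fm <- format(cm)
  write_tsv(data.frame(group = rownames(fm), fm, check.names = FALSE),
            emit("matrix", out("conservation_matrix.tsv")))
  core <- compute_core_set(cm)
  write_tsv(as.data.frame(core), emit("coreset", out("core_set.tsv")))
  log_line("coreset", nrow(core), " core groups")
  dup <- duplication_report(cm)
  dup_df <- do.call(rbind, lapply(names(dup), function(s)
    if (length(dup[[s]])) data.frame(species = s, group = names(dup[[s]]),
                                     copies = as.integer(dup[[s]]))))
  if (is.null(dup_df))
    dup_df <- data.frame(species = character(), group = character(),
                         copies = integer())
  write_tsv(dup_df, emit("duplications", out("duplications.tsv")))

  res$matrix <- cm
  res$core_set <- core
  res$duplications <- dup
  write_tsv(manifest, out("manifest.tsv"))
  res$manifest <- manifest
  log_line("done", nrow(manifest), " artifacts in ",
           format(Sys.time() - t0, digits = 3))
  invisible(res)
}

#' Group-recovery experiment over simulated families
#'
#' Runs the full pipeline over independently seeded simulated families and
#' pools the fraction of genes assigned to their true ortholog group.
#' Replicates whose family goes extinct or retains fewer than three
#' eligible sequences (no tree possible) are reported as degenerate and
#' excluded from the pooled rate.
#'
#' @param seeds integer vector of simulation seeds.
#' @param config_for function mapping a seed to a [simulation_config()].
#' @param bootstrap_replicates bootstrap replicates per pipeline run.
#' @param verbose print one line per seed.
#' @return list with `rate` (pooled over genes), `per_seed` data frame and
#'   `degenerate` (skipped seeds).
#' @export
recovery_experiment <- function(seeds = 1:20,
                                config_for = function(s)
                                  simulation_config(seed = s),
                                bootstrap_replicates = 100L,
                                verbose = FALSE) {
  rows <- list(); degenerate <- integer(0)
  for (s in seeds) {
    fam <- simulate_family(config_for(s))
    res <- tryCatch({
      d <- emit_dataset(fam, file.path(tempfile("recovery_"), s))
      cfg <- pipeline_config(
        catalog = d[["catalog"]], registry = d[["registry"]],
        fasta = d[["fasta"]], out_dir = file.path(dirname(d[["catalog"]]),
                                                  "out"),
        bootstrap_replicates = bootstrap_replicates, seed = s,
        verbose = FALSE)
      run_pipeline(cfg)
    }, error = function(e) e)
    if (inherits(res, "error") || nrow(fam$genes) == 0L) {
      degenerate <- c(degenerate, s)
      if (verbose) message("seed ", s, ": degenerate (",
                           conditionMessage(res), ")")
      next
    }
    rr <- group_recovery_rate(res$groups, fam)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, n_assigned = nrow(rr$detail), rate = rr$rate)
    if (verbose) message("seed ", s, ": rate ", round(rr$rate, 3))
  }
  per_seed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = integer(), n_assigned = integer(), rate = numeric())
  list(rate = sum(per_seed$rate * per_seed$n_assigned) /
         max(1L, sum(per_seed$n_assigned)),
       per_seed = per_seed, degenerate = degenerate)
}
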