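# Synthetic gene families with known ground truth.
#
# Emulates what the study mined from genome databases: a multi-species
# protein family shaped by lineage-specific duplications and losses
# (birth-death along a species tree), sequence divergence under an
# amino-acid model, variable domain architectures, and proteolytically
# inactivated members with mutated catalytic triads.  Every simulated gene
# carries a conserved protease-domain cassette (the bundled PD profile
# consensus, held invariant as the strongly conserved catalytic core)
# followed by the evolved variable region; inactivation mutates one triad
# anchor inside the cassette, so the validation round trip runs on real
# detection.

#' Simulation configuration
#'
#' Defaults describe a plant-like study: five species, moderate divergence,
#' duplication rate 0.3 and loss rate 0.1 per unit branch length, 300
#' evolved columns, ~15% of genes proteolytically inactivated, and an
#' architecture palette mirroring the arrangements seen across the family's
#' clades.
#'
#' @param n_species number of ingroup species (>= 1).
#' @param species_tree_height expected substitutions/site from ingroup root
#'   to tips.
#' @param duplication_rate,loss_rate birth-death rates per unit branch
#'   length.
#' @param sequence_length evolved columns per gene (the conserved cassette
#'   adds its own length).
#' @param model a [rate_model()].
#' @param inactivation_fraction fraction of genes whose catalytic triad is
#'   mutated.
#' @param architecture_palette named numeric vector: architecture string ->
#'   sampling weight.
#' @param arch_switch_prob probability that a duplication switches the
#'   daughter architecture.
#' @param include_outgroup attach one event-free outgroup lineage
#'   (`"Out"`) above the ingroup root.
#' @param outgroup_stem stem length above the ingroup root for the
#'   outgroup split.
#' @param n_root_genes ancestral gene lineages at the species-tree root
#'   (default 1).
#' @param seed integer seed.
#' @export
simulation_config <- function(n_species = 5L, species_tree_height = 0.6,
                              duplication_rate = 0.3, loss_rate = 0.1,
                              sequence_length = 300L, model = wag_model(),
                              inactivation_fraction = 0.15,
                              architecture_palette = c(
                                "PD-PDZ" = 0.35, "PD-PDZ-PDZ" = 0.3,
                                "PD" = 0.1,
                                "PD-PDZ-PDZ-PD_ia-PDZ-PDZ" = 0.15,
                                "NT-PD" = 0.1),
                              arch_switch_prob = 0.02,
                              include_outgroup = TRUE, outgroup_stem = 0.5,
                              n_root_genes = 1L, seed = 1L) {
  stopifnot(n_species >= 1L, duplication_rate >= 0, loss_rate >= 0,
            inactivation_fraction >= 0, inactivation_fraction <= 1,
            sequence_length >= 1L, n_root_genes >= 1L)
  as.list(environment())
}

#' Simulate a species tree
#'
#' Random coalescent-style labelled topology (ingroup tips `S1`..`Sn`),
#' branch lengths rescaled to the configured root-to-tip height, with an
#' optional outgroup lineage attached above the ingroup root.
#' Deterministic per seed.
#'
#' @param cfg a [simulation_config()].
#' @return a rooted `phylo`.
#' @export
simulate_species_tree <- function(cfg) {
  set.seed(cfg$seed)
  h <- cfg$species_tree_height
  n <- cfg$n_species
  if (n == 1L) {
    core <- paste0("S1:", h)
  } else {
    tr <- ape::rcoal(n, tip.label = paste0("S", seq_len(n)))
    depth <- max(ape::node.depth.edgelength(tr)[seq_len(n)])
    tr$edge.length <- tr$edge.length * h / depth
    core <- sub(";$", "", ape::write.tree(tr))
    core <- paste0(core, ":0")            # will carry the stem when rooted
  }
  if (!cfg$include_outgroup) {
    if (n == 1L) return(ape::read.tree(text = paste0("(", core, ");")))
    tr <- ape::read.tree(text = paste0(sub(":0$", "", core), ";"))
    return(tr)
  }
  stem <- cfg$outgroup_stem
  core <- sub(":0$", paste0(":", stem), core)
  if (n == 1L) core <- paste0("S1:", h + stem)
  ape::read.tree(text = paste0("(", core, ",Out:", h + stem, ");"))
}

#' Simulate a gene tree by birth-death along a species tree
#'
#' Each of `n_root_genes` ancestral genes enters the species-tree root and
#' evolves down every branch: duplications (rate `dup_rate`) bifurcate the
#' gene lineage within the species lineage, losses (rate `loss_rate`) prune
#' it, speciations copy every surviving lineage into both descendant
#' species.  The outgroup branch is kept event-free (a single orthologous
#' copy) so rooting is always well-defined.  Architectures are inherited
#' along lineages and may switch at duplications.
#'
#' @param species_tree rooted `phylo` from [simulate_species_tree()].
#' @param dup_rate,loss_rate events per unit branch length.
#' @param seed integer seed.
#' @param palette,switch_prob,n_root_genes see [simulation_config()].
#' @param outgroup_label tip excluded from birth-death events.
#' @return list with `tree` (gene tree `phylo`, NULL if < 2 surviving
#'   genes), `genes` (data frame `id`, `species`, `true_group`,
#'   `architecture`, `active`), `extinct` flag.
#' @export
simulate_gene_tree <- function(species_tree, dup_rate, loss_rate, seed = 1L,
                               palette = c("PD-PDZ" = 1),
                               switch_prob = 0, n_root_genes = 1L,
                               outgroup_label = "Out") {
  set.seed(seed)
  st <- species_tree
  ntip <- ape::Ntip(st)
  counter <- new.env(parent = emptyenv())
  genes <- list()

  sample_arch <- function() sample(names(palette), 1L, prob = palette)
  switch_arch <- function(arch) {
    if (length(palette) > 1L && runif(1L) < switch_prob) {
      others <- setdiff(names(palette), arch)
      sample(others, 1L, prob = palette[others])
    } else arch
  }
  new_gene <- function(species, group, arch) {
    k <- (get0(species, counter) %||% 0L) + 1L
    assign(species, k, counter)
    id <- paste0(species, "_g", k)
    genes[[length(genes) + 1L]] <<- data.frame(
      id = id, species = species, true_group = group,
      architecture = arch, active = TRUE)
    id
  }

  # one gene lineage entering the branch above species node `node` with
  # `rem` branch length to go; returns list(nwk, len) or NULL on loss
  descend <- function(node, rem, group, arch) {
    is_out <- node <= ntip && st$tip.label[node] == outgroup_label
    rate <- if (is_out) 0 else dup_rate + loss_rate
    used <- 0
    repeat {
      dt <- if (rate > 0) rexp(1L, rate) else Inf
      if (dt >= rem - used) {
        below <- at_node(node, group, arch)
        if (is.null(below)) return(NULL)
        below$len <- below$len + rem
        return(below)
      }
      used <- used + dt
      if (runif(1L) < dup_rate / (dup_rate + loss_rate)) {
        a <- descend_from(node, rem - used, group, arch)
        b <- descend_from(node, rem - used, group, switch_arch(arch))
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a) || is.null(b)) {
          keep <- if (is.null(a)) b else a
          keep$len <- keep$len + used
          return(keep)
        }
        return(list(nwk = sprintf("(%s:%.10g,%s:%.10g)D",
                                  a$nwk, a$len, b$nwk, b$len),
                    len = used))
      }
      return(NULL)   # loss
    }
  }
  # re-entry helper: continue within the same species branch
  descend_from <- function(node, rem, group, arch)
    descend(node, rem, group, arch)

  # gene lineage arriving exactly at species node `node`
  at_node <- function(node, group, arch) {
    if (node <= ntip)
      return(list(nwk = new_gene(st$tip.label[node], group, arch), len = 0))
    kid_edges <- which(st$edge[, 1L] == node)
    parts <- list()
    for (e in kid_edges) {
      r <- descend(st$edge[e, 2L], st$edge.length[e], group, arch)
      if (!is.null(r)) parts[[length(parts) + 1L]] <- r
    }
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    list(nwk = sprintf("(%s)", paste(vapply(parts, function(p)
      sprintf("%s:%.10g", p$nwk, p$len), ""), collapse = ",")), len = 0)
  }

  root <- ntip + 1L
  lineages <- list()
  for (g in seq_len(n_root_genes)) {
    r <- at_node(root, paste0("G", g), sample_arch())
    if (!is.null(r)) lineages[[length(lineages) + 1L]] <- r
  }
  gene_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(id = character(), species = character(),
               true_group = character(), architecture = character(),
               active = logical())
  if (!length(lineages)) {
    warning("gene family went extinct")
    return(list(tree = NULL, genes = gene_df, extinct = TRUE))
  }
  nwk <- if (length(lineages) == 1L) {
    l <- lineages[[1L]]
    if (grepl("^\\(", l$nwk)) paste0(l$nwk, ";")
    else sprintf("(%s:%.10g);", l$nwk, l$len)
  } else {
    sprintf("(%s);", paste(vapply(lineages, function(p)
      sprintf("%s:%.10g", p$nwk, p$len), ""), collapse = ","))
  }
  tree <- if (nrow(gene_df) >= 2L) ape::read.tree(text = nwk) else NULL
  list(tree = tree, genes = gene_df, extinct = FALSE)
}

#' Evolve sequences along a gene tree
#'
#' Root sequence drawn from the model's equilibrium frequencies; residues
#' evolve independently per site with transition probabilities from the
#' model (no indels, fixed length).  Standard sequence simulation delegated
#' to phangorn's engine.
#'
#' @param gene_tree a `phylo`.
#' @param model a [rate_model()].
#' @param length number of columns.
#' @param seed integer seed.
#' @return named character vector, gene id -> sequence.
#' @export
evolve_sequences <- function(gene_tree, model = wag_model(), length = 300L,
                             seed = 1L) {
  stopifnot(length >= 1L)
  set.seed(seed)
  if (ape::Ntip(gene_tree) == 1L) {
    root <- sample(AA20, length, replace = TRUE, prob = model$freqs)
    P <- transition_prob(model, sum(gene_tree$edge.length))
    tip <- vapply(root, function(a) sample(AA20, 1L, prob = P[a, ]), "")
    return(setNames(paste(tip, collapse = ""), gene_tree$tip.label))
  }
  sim <- phangorn::simSeq(gene_tree, l = length, Q = model$rates,
                          bf = unname(model$freqs), type = "AA")
  M <- toupper(as.character(sim))
  setNames(apply(M, 1L, paste, collapse = ""), rownames(M))
}

TRIAD_SUBSTITUTION <- c(H = "L", D = "N", S = "A")

#' Mutate catalytic triads in a fraction of simulated genes
#'
#' A seeded random subset of genes (proportion `fraction`, rounded) has one
#' triad anchor residue in its protease-domain cassette substituted with a
#' non-triad residue, and its active flag cleared (architecture PD ->
#' PD_ia).
#'
#' @param family a `deg_family` from [simulate_family()].
#' @param fraction proportion of genes to inactivate, in `[0, 1]`.
#' @param seed integer seed.
#' @return the modified `deg_family`.
#' @export
inject_inactivation <- function(family, fraction, seed = 1L) {
  stopifnot(inherits(family, "deg_family"), fraction >= 0, fraction <= 1)
  set.seed(seed)
  # outgroup sequences model curated, known-active reference proteins and
  # are exempt from inactivation (they must support rooting)
  pool <- family$genes$id[family$genes$species != "Out"]
  n <- length(pool)
  if (n == 0L) return(family)
  k <- round(fraction * n)
  if (k == 0L) return(family)
  ids <- sort(sample(pool, k))
  anchors <- family$pd_anchors
  for (id in ids) {
    res <- sample(names(anchors), 1L)
    pos <- family$cassette_offset + anchors[[res]] - 1L
    s <- family$sequences[[id]]
    substr(s, pos, pos) <- TRIAD_SUBSTITUTION[[res]]
    family$sequences[[id]] <- s
    i <- match(id, family$genes$id)
    family$genes$active[i] <- FALSE
    family$genes$architecture[i] <-
      sub("(^|-)PD(-|$)", "\\1PD_ia\\2", family$genes$architecture[i])
  }
  family
}

#' Simulate a complete gene family with ground truth
#'
#' Orchestrates [simulate_species_tree()], [simulate_gene_tree()],
#' [evolve_sequences()] and [inject_inactivation()], prepends the conserved
#' protease-domain cassette, and designates the reference species (the
#' first ingroup species, in label order, with at least one active gene)
#' whose active genes receive established anchor names `Deg1`, `Deg2`, ...
#'
#' @param cfg a [simulation_config()].
#' @return object of class `deg_family`: `species_tree`, `gene_tree`,
#'   `genes` (with `anchor_name`), `sequences`, `cassette_offset`,
#'   `pd_anchors`, `reference_species`, `config`.
#' @export
simulate_family <- function(cfg = simulation_config()) {
  st <- simulate_species_tree(cfg)
  gt <- simulate_gene_tree(st, cfg$duplication_rate, cfg$loss_rate,
                           seed = cfg$seed + 1L,
                           palette = cfg$architecture_palette,
                           switch_prob = cfg$arch_switch_prob,
                           n_root_genes = cfg$n_root_genes)
  pd <- builtin_profiles()$PD
  fam <- structure(list(species_tree = st, gene_tree = gt$tree,
                        genes = gt$genes, sequences = character(0),
                        cassette_offset = 1L, pd_anchors = pd$anchors,
                        reference_species = NA_character_, config = cfg),
                   class = "deg_family")
  if (nrow(gt$genes) == 0L) return(fam)
  evolved <- if (is.null(gt$tree)) {
    set.seed(cfg$seed + 2L)
    setNames(paste(sample(AA20, cfg$sequence_length, replace = TRUE,
                          prob = cfg$model$freqs), collapse = ""),
             gt$genes$id)
  } else evolve_sequences(gt$tree, cfg$model, cfg$sequence_length,
                          seed = cfg$seed + 2L)
  fam$sequences <- setNames(paste0(pd$consensus, evolved[gt$genes$id]),
                            gt$genes$id)
  fam <- inject_inactivation(fam, cfg$inactivation_fraction,
                             seed = cfg$seed + 3L)
  # reference species: first ingroup species (label order) with active genes
  g <- fam$genes
  ingroup <- sort(setdiff(unique(g$species), "Out"))
  ref <- ingroup[vapply(ingroup, function(s)
    any(g$active[g$species == s]), TRUE)][1L]
  fam$reference_species <- ref
  fam$genes$anchor_name <- ""
  if (!is.na(ref)) {
    sel <- which(g$species == ref & g$active)
    sel <- sel[order(g$id[sel])]
    fam$genes$anchor_name[sel] <- paste0("Deg", seq_along(sel))
  }
  fam
}

#' @export
print.deg_family <- function(x, ...) {
  cat("Simulated gene family:", nrow(x$genes), "genes in",
      length(unique(x$genes$species)), "species\n")
  if (nrow(x$genes)) {
    cat("  inactive:", sum(!x$genes$active),
        "| reference species:", x$reference_species, "\n")
  }
  invisible(x)
}

#' Write a simulated family as a loadable dataset
#'
#' Emits FASTA sequences, a catalog + registry loadable by
#' [load_catalog()], the ground-truth table and both trees.  Declared
#' architectures come from the truth (as database annotations would);
#' activity is left undeclared so the pipeline exercises sequence-based
#' validation.
#'
#' @param family a non-empty `deg_family`.
#' @param dir output directory (created).
#' @return named character vector of written paths.
#' @export
emit_dataset <- function(family, dir) {
  stopifnot(inherits(family, "deg_family"))
  if (nrow(family$genes) == 0L) stop("cannot emit an empty family")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- family$genes
  paths <- c(fasta = file.path(dir, "genes.fasta"),
             catalog = file.path(dir, "catalog.tsv"),
             registry = file.path(dir, "registry.tsv"),
             truth = file.path(dir, "truth.tsv"),
             species_tree = file.path(dir, "species_tree.nwk"),
             gene_tree = file.path(dir, "gene_tree.nwk"))
  write_fasta(family$sequences[g$id], paths[["fasta"]])
  cat_df <- data.frame(
    id = g$id, species = g$species,
    length_aa = nchar(family$sequences[g$id]),
    architecture = g$architecture, prior_names = "",
    anchor_name = g$anchor_name, active = "", activity_reason = "",
    not_family = 0L, group = "", proposed_name = "")
  write_tsv(cat_df, paths[["catalog"]])
  species <- sort(unique(g$species))
  reg <- data.frame(code = species,
                    name = paste("Simulated species", species),
                    is_outgroup = as.integer(species == "Out"),
                    is_reference_anchor =
                      as.integer(species == family$reference_species))
  write_tsv(reg, paths[["registry"]])
  write_tsv(g[, c("id", "species", "true_group", "active", "architecture",
                  "anchor_name")], paths[["truth"]])
  write_newick(family$species_tree, paths[["species_tree"]])
  if (!is.null(family$gene_tree))
    write_newick(family$gene_tree, paths[["gene_tree"]])
  paths
}

#' Fraction of genes assigned to their true ortholog group
#'
#' A gene counts as correctly assigned when its group is anchored (or
#' group-like) on an anchor belonging to the gene's true lineage; genes
#' whose true lineage has no reference-species anchor count as correct when
#' they end up in a like group.
#'
#' @param groups a `deg_groups` from [assign_ortholog_groups()].
#' @param family the generating `deg_family` (ground truth).
#' @return list with `rate` and the per-gene `detail` data frame.
#' @export
group_recovery_rate <- function(groups, family) {
  asn <- groups$assignment
  tg <- family$genes$true_group[match(asn$id, family$genes$id)]
  ref <- family$reference_species
  anchors <- family$genes[family$genes$species == ref &
                            nzchar(family$genes$anchor_name), , drop = FALSE]
  correct <- vapply(seq_len(nrow(asn)), function(i) {
    names_tg <- anchors$anchor_name[anchors$true_group == tg[i]]
    if (!length(names_tg)) return(asn$status[i] == "like")
    asn$status[i] %in% c("anchored", "group_like") &&
      asn$group[i] %in% names_tg
  }, TRUE)
  list(rate = mean(correct),
       detail = data.frame(asn, true_group = tg, correct = correct))
}
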