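# Tree inference over protease-domain alignments.
#
# Distance, parsimony and maximum-likelihood inference are standard steps
# and delegate to the ape and phangorn engines behind this module's
# surface: neighbour joining (ape::nj) on the module's own alignment
# distances, Fitch parsimony scores (phangorn::parsimony), and Felsenstein
# pruning likelihood with branch-length optimisation and NNI topology
# search (phangorn::pml / optim.pml) under this package's rate models.
# Nonparametric bootstrap supports are computed by this module's own
# column-resampling protocol so that seeds and split matching are fully
# specified.

BL_MIN <- 1e-8
BL_MAX <- 50

as_phydat <- function(msa) {
  M <- unclass(msa)
  phangorn::phyDat(M, type = "AA")
}

pml_fit <- function(tree, msa, model) {
  check_tree_vs_msa(tree, msa)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  phangorn::pml(tree, as_phydat(msa), bf = unname(model$freqs),
                Q = model$rates, k = 1)
}

check_tree_vs_msa <- function(tree, msa) {
  if (!setequal(tree$tip.label, rownames(msa)))
    stop("tree leaves and alignment rows do not match")
}

#' Pairwise distances from an alignment
#'
#' Pairwise-deletion distances: for each pair, p is the mismatch fraction
#' over columns in which both rows hold an unambiguous residue (non-gap,
#' non-X).  `mode = "poisson"` applies the Poisson correction
#' d = -ln(1 - p), clamped at 10 for saturated pairs (flagged in the
#' `"saturated"` attribute).
#'
#' @param msa a `deg_msa` with at least two rows.
#' @param mode `"poisson"` (corrected, default) or `"p"` (raw mismatch
#'   fraction).
#' @return symmetric distance matrix with a `"saturated"` attribute listing
#'   clamped pairs.
#' @export
pairwise_distances <- function(msa, mode = c("poisson", "p")) {
  mode <- match.arg(mode)
  M <- unclass(msa)
  if (nrow(M) < 2L) stop("need at least two rows")
  ids <- rownames(M)
  ok <- matrix(M %in% AA20, nrow(M), ncol(M))
  D <- matrix(0, nrow(M), nrow(M), dimnames = list(ids, ids))
  saturated <- character(0)
  for (i in seq_len(nrow(M) - 1L)) for (j in (i + 1L):nrow(M)) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("no comparable columns between '", ids[i], "' and '", ids[j], "'")
    p <- mean(M[i, comp] != M[j, comp])
    d <- if (mode == "p") p else if (p >= 1 - exp(-10)) {
      saturated <- c(saturated, paste(ids[i], ids[j], sep = "/"))
      10
    } else -log(1 - p)
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- saturated
  D
}

#' Neighbour-joining tree
#'
#' Standard NJ agglomeration (ape's implementation) on a symmetric distance
#' matrix.  Ids are put in lexicographic order first so that ties resolve
#' reproducibly; negative intermediate branch lengths are clamped to zero
#' (flagged in the `"clamped"` attribute).
#'
#' @param D symmetric distance matrix with dimnames (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbour joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must have dimnames")
  ord <- order(rownames(D))
  tr <- ape::nj(D[ord, ord])
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of state changes over all columns (Fitch algorithm);
#' gaps and X are treated as missing (compatible with every state).
#'
#' @param tree a `phylo` whose tips are the alignment rows.
#' @param msa a `deg_msa`.
#' @return integer score.
#' @export
fitch_parsimony_score <- function(tree, msa) {
  check_tree_vs_msa(tree, msa)
  as.integer(phangorn::parsimony(tree, as_phydat(msa), method = "fitch"))
}

#' Log-likelihood of a tree under an amino-acid model
#'
#' Felsenstein pruning with independent sites; gap and X cells are
#' marginalised (all-ones partial vectors); transition probabilities come
#' from the matrix exponential of the normalised rate matrix.
#'
#' @param tree `phylo` with branch lengths (all `>= 0`).
#' @param msa a `deg_msa` whose rows are the tree's tips.
#' @param model a [rate_model()].
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, msa, model = wag_model()) {
  fit <- pml_fit(tree, msa, model)
  ll <- fit$logLik
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Optimise branch lengths by maximum likelihood
#'
#' Iterative per-branch optimisation until the log-likelihood improvement
#' falls below `tol` or `max_sweeps` sweeps; the returned likelihood is
#' never below the input likelihood.  Branch lengths are bounded to
#' `[1e-8, 50]` (boundary clamps flagged via the `"clamped_branches"`
#' attribute).
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum optimisation sweeps.
#' @return the tree with optimised branch lengths; attribute `"loglik"`.
#' @export
optimize_branch_lengths <- function(tree, msa, model = wag_model(),
                                    tol = 1e-6, max_sweeps = 20L) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (length(tree$tip.label) == 2L) {
    # a two-leaf tree has a single path; optimise its total length directly
    f <- function(s) {
      t2 <- tree
      t2$edge.length <- rep(s / length(t2$edge.length),
                            length(t2$edge.length))
      log_likelihood(t2, msa, model)
    }
    opt <- stats::optimize(f, c(2 * BL_MIN, 2 * BL_MAX), maximum = TRUE,
                           tol = tol)
    out <- tree
    out$edge.length <- rep(opt$maximum / length(tree$edge.length),
                           length(tree$edge.length))
    if (f(2 * BL_MIN) >= opt$objective) out$edge.length[] <- BL_MIN
    if (f(2 * BL_MAX) > max(opt$objective, f(2 * BL_MIN)))
      out$edge.length[] <- BL_MAX
    attr(out, "loglik") <- log_likelihood(out, msa, model)
    return(out)
  }
  fit <- pml_fit(tree, msa, model)
  o <- suppressWarnings(phangorn::optim.pml(
    fit, optEdge = TRUE,
    control = phangorn::pml.control(epsilon = tol, maxit = max_sweeps,
                                    trace = 0)))
  if (!is.finite(o$logLik)) stop("non-finite log-likelihood")
  out <- o$tree
  clamped <- sum(out$edge.length < BL_MIN | out$edge.length > BL_MAX)
  out$edge.length <- pmin(pmax(out$edge.length, BL_MIN), BL_MAX)
  attr(out, "loglik") <- max(o$logLik, fit$logLik)
  attr(out, "clamped_branches") <- clamped
  out
}

#' Nearest-neighbour-interchange topology search
#'
#' Hill-climbs over NNI rearrangements (with branch-length re-optimisation)
#' until no rearrangement improves the likelihood.  Trees with fewer than
#' four leaves have no internal edge and are returned unchanged.
#'
#' @inheritParams optimize_branch_lengths
#' @return the best tree found; attribute `"loglik"`.
#' @export
nni_search <- function(tree, msa, model = wag_model(), tol = 1e-6) {
  if (length(tree$tip.label) < 4L) {
    attr(tree, "loglik") <- log_likelihood(tree, msa, model)
    return(tree)
  }
  tree <- ape::unroot(tree)
  fit <- pml_fit(tree, msa, model)
  o <- tryCatch(
    suppressWarnings(phangorn::optim.pml(
      fit, optEdge = TRUE, optNni = TRUE,
      control = phangorn::pml.control(epsilon = tol, maxit = 20L,
                                      trace = 0))),
    error = function(e) {
      # degenerate data (e.g. near-zero information) can collapse internal
      # edges during the rearrangement search; keep the topology and
      # optimise branch lengths only
      warning("NNI search degenerate (", conditionMessage(e),
              "); keeping the starting topology")
      suppressWarnings(phangorn::optim.pml(
        fit, optEdge = TRUE,
        control = phangorn::pml.control(epsilon = tol, maxit = 20L,
                                        trace = 0)))
    })
  out <- o$tree
  out$edge.length <- pmin(pmax(out$edge.length, BL_MIN), BL_MAX)
  attr(out, "loglik") <- o$logLik
  out
}

#' Infer a maximum-likelihood tree
#'
#' Pipeline: neighbour-joining starting tree on Poisson-corrected distances,
#' branch-length optimisation, then NNI search.  Deterministic given the
#' seed.
#'
#' @param msa a `deg_msa` (>= 3 rows).
#' @param model a [rate_model()].
#' @param seed integer seed.
#' @return unrooted `phylo`; attribute `"loglik"`.
#' @export
infer_ml_tree <- function(msa, model = wag_model(), seed = 1L) {
  if (nrow(msa) < 3L) stop("need at least 3 sequences")
  set.seed(seed)
  start <- neighbor_joining(pairwise_distances(msa, "poisson"))
  start$edge.length[start$edge.length < BL_MIN] <- BL_MIN
  if (length(start$tip.label) < 4L) {
    out <- optimize_branch_lengths(start, msa, model)
    return(out)
  }
  nni_search(start, msa, model)
}

#' Bootstrap configuration
#'
#' @param replicates number of nonparametric bootstrap replicates
#'   (default 100).
#' @param seed integer seed; replicate r draws its columns under seed
#'   `seed + r`.
#' @export
bootstrap_config <- function(replicates = 100L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  list(replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Nonparametric bootstrap supports for an ML tree
#'
#' Columns are resampled with replacement per replicate and a full ML tree
#' is inferred per replicate; the support of each internal edge of the
#' point-estimate tree is the percentage of replicate trees containing the
#' same bipartition.  Supports are stored as node labels (internal edges
#' only; the root is unlabelled) and the full split table is attached as
#' attribute `"split_support"`.
#'
#' @inheritParams infer_ml_tree
#' @param config a [bootstrap_config()].
#' @param tree optional point-estimate tree; inferred from `msa` if absent.
#' @return the point-estimate `phylo` with per-edge supports in
#'   `node.label`.
#' @export
bootstrap_supports <- function(msa, model = wag_model(),
                               config = bootstrap_config(), tree = NULL) {
  if (is.null(tree)) tree <- infer_ml_tree(msa, model, seed = config$seed)
  tree <- ape::unroot(tree)
  M <- unclass(msa)
  splits <- lapply(seq_len(config$replicates), function(r) {
    set.seed(config$seed + r)
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    rep_msa <- structure(M[, cols, drop = FALSE], class = "deg_msa")
    rep_tree <- infer_ml_tree(rep_msa, model, seed = config$seed + r)
    split_strings(rep_tree)
  })
  counts <- table(unlist(splits))
  annotate_supports(tree, counts, config$replicates)
}

# canonical strings for the non-trivial bipartitions of a tree
split_strings <- function(tree) {
  tree <- ape::unroot(tree)
  all_tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (min(length(side), length(all_tips) - length(side)) < 2L) next
    out <- c(out, canonical_split(side, all_tips))
  }
  unique(out)
}

canonical_split <- function(side, all_tips) {
  side <- sort(side)
  other <- sort(setdiff(all_tips, side))
  keep <- if (all_tips[1L] %in% side) other else side
  paste(keep, collapse = "\r")
}

# write split supports (%) onto a tree's internal node labels
annotate_supports <- function(tree, counts, replicates) {
  all_tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  node_lab <- character(tree$Nnode)
  support <- numeric(0)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (min(length(side), length(all_tips) - length(side)) < 2L) next
    key <- canonical_split(side, all_tips)
    pct <- 100 * (if (key %in% names(counts)) counts[[key]] else 0) /
      replicates
    node_lab[k] <- format(pct, trim = TRUE)
    support[key] <- pct
  }
  tree$node.label <- node_lab
  attr(tree, "split_support") <- support
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two trees (taken as
#' unrooted).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Read / write Newick trees
#'
#' Numeric internal-node labels are bootstrap supports by convention and
#' survive the round trip, as do branch lengths (fixed decimal precision).
#'
#' @param text Newick string (or a file path for `read_newick(file = )`).
#' @param file optional path to read from instead of `text`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(file)) ape::read.tree(file)
    else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error",
         if (!is.null(text)) paste0(" in: ", substr(text, 1, 60)))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @param path output file; if NULL the Newick string is returned.
#' @param digits decimal precision for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 8L) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}
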