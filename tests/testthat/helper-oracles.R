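# Independent oracles used across the suite: brute-force enumeration of
# global alignments, Fitch assignments and likelihood summations, plus
# small fixture builders.  Oracles never call the code paths they check.

fixture_catalog <- function() {
  load_catalog(degphylo_example("catalog_plants.tsv"),
               degphylo_example("registry_plants.tsv"))
}

random_peptide <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive optimum over all global alignments of a and b; scores each
# candidate from its gapped strings (gap run of length k costs
# open + k * extend), independently of any DP recurrence
enum_align_score <- function(a, b, m, g) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  score_alignment <- function(ga, gb) {
    s <- 0
    for (k in seq_along(ga))
      if (ga[k] != "-" && gb[k] != "-") s <- s + m[ga[k], gb[k]]
    for (row in list(ga, gb)) {
      r <- rle(row == "-")
      runs <- r$lengths[r$values]
      s <- s - sum(g$open + runs * g$extend)
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_alignment(ga, gb))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, c(ga, av[i]), c(gb, bv[j]))
    if (i <= length(av)) rec(i + 1, j, c(ga, av[i]), c(gb, "-"))
    if (j <= length(bv)) rec(i, j + 1, c(ga, "-"), c(gb, bv[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# minimum state changes over a column by exhaustive internal-state
# assignment; missing tip states ("-"/"X") are free
brute_fitch_column <- function(tree, states) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  obs <- unique(states[!states %in% c("-", "X")])
  if (length(obs) <= 1) return(0)
  free_tips <- which(states %in% c("-", "X"))
  vars <- c(nt + seq_len(nn), free_tips)
  grids <- rep(list(obs), length(vars))
  grid <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  tip_state <- states
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= nt && !(node %in% free_tips)) return(tip_state[node])
      grid[r, match(node, vars)]
    }
    ch <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign_state(tree$edge[e, 1])
      c2 <- assign_state(tree$edge[e, 2])
      if (p != c2) ch <- ch + 1
    }
    best <- min(best, ch)
  }
  best
}

brute_fitch <- function(tree, msa) {
  M <- unclass(msa)[tree$tip.label, , drop = FALSE]
  sum(vapply(seq_len(ncol(M)), function(j)
    brute_fitch_column(tree, M[, j]), 0))
}

# site likelihood by summation over all unknown node states, transition
# probabilities from Matrix::expm's Pade scaling-and-squaring (independent
# of the package's eigendecomposition route)
brute_loglik <- function(tree, msa, model) {
  skip_if_not_installed("Matrix")
  M <- unclass(msa)[tree$tip.label, , drop = FALSE]
  aa <- rownames(model$Q)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(model$Q * tree$edge.length[e])))
  root <- nt + 1
  total <- 0
  for (j in seq_len(ncol(M))) {
    states <- M[, j]
    free_tips <- which(states %in% c("-", "X"))
    vars <- c(nt + seq_len(nn), free_tips)
    grid <- do.call(expand.grid,
                    c(rep(list(aa), length(vars)), stringsAsFactors = FALSE))
    lik <- 0
    for (r in seq_len(nrow(grid))) {
      st <- function(node) {
        if (node <= nt && !(node %in% free_tips)) return(states[node])
        grid[r, match(node, vars)]
      }
      term <- model$freqs[[st(root)]]
      for (e in seq_len(nrow(tree$edge)))
        term <- term * P[[e]][match(st(tree$edge[e, 1]), aa),
                              match(st(tree$edge[e, 2]), aa)]
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# small catalog for nomenclature tests built in code
toy_catalog <- function(records, reference = "At", outgroup = "Syn") {
  species <- unique(c(records$species, reference, outgroup))
  reg <- data.frame(code = species, name = paste("Species", species),
                    is_outgroup = species == outgroup,
                    is_reference_anchor = species == reference)
  class(reg) <- c("deg_registry", "data.frame")
  defaults <- data.frame(
    id = records$id, species = records$species,
    length_aa = if (is.null(records$length_aa)) 100L else records$length_aa,
    architecture = records$architecture %||% "",
    prior_names = "", anchor_name = records$anchor_name %||% "",
    active = NA, activity_reason = "",
    not_family = records$not_family %||% FALSE,
    group = "", proposed_name = "")
  structure(list(registry = reg, records = defaults,
                 provenance = "built in test"),
            class = "deg_catalog")
}

msa_from_sim <- function(seqs) {
  M <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(M) <- names(seqs)
  structure(M, class = "deg_msa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
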