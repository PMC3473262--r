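test_that("pairwise distances follow the Poisson correction and clamp", {
  a <- deg_msa(c(x = "ARNDARND", y = "ARNDARND"))
  expect_equal(unname(pairwise_distances(a)["x", "y"]), 0)

  b <- deg_msa(c(x = "ARNDARND", y = "ARNDRNDA"))   # p = 0.5
  expect_equal(unname(pairwise_distances(b)["x", "y"]), -log(0.5))
  expect_equal(unname(pairwise_distances(b, "p")["x", "y"]), 0.5)

  # fully saturated pair clamps at 10 with a flag
  c2 <- deg_msa(c(x = "AAAA", y = "RRRR"))
  D <- pairwise_distances(c2)
  expect_equal(unname(D["x", "y"]), 10)
  expect_match(attr(D, "saturated"), "x/y")

  # gaps and X are pairwise-deleted; a pair with no comparable column errors
  d2 <- deg_msa(c(x = "A--X", y = "-RR-"))
  expect_error(pairwise_distances(d2), "x.*y")

  e2 <- deg_msa(c(x = "AR-N", y = "AR-D", z = "ARKN"))
  expect_equal(unname(pairwise_distances(e2, "p")["x", "y"]), 1 / 3)
})

test_that("neighbour joining solves three taxa in closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)   # 1
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)   # 2
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)   # 3
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbour joining recovers additive distance matrices exactly", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n)
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 2)
    D <- stats::cophenetic(gen)
    rec <- neighbor_joining(D)
    expect_equal(rf_distance(rec, gen), 0L)
    expect_equal(stats::cophenetic(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  # all-equal distances: deterministic, reproducible topology
  E <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(E) <- 0
  expect_equal(write_newick(neighbor_joining(E)),
               write_newick(neighbor_joining(E)))
})

test_that("Fitch parsimony equals exhaustive assignment", {
  t4 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  const <- deg_msa(setNames(rep("AA", 4), LETTERS[1:4]))
  expect_equal(fitch_parsimony_score(t4, const), 0L)
  split2 <- deg_msa(c(A = "A", B = "A", C = "S", D = "S"))
  expect_equal(fitch_parsimony_score(t4, split2), 1L)

  set.seed(17)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    M <- matrix(sample(c("A", "R", "N", "D", "-"), n * 3, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), n, 3,
                dimnames = list(tr$tip.label, NULL))
    msa <- structure(M, class = "deg_msa")
    expect_equal(fitch_parsimony_score(tr, msa), brute_fitch(tr, msa),
                 info = paste("case", i))
  }
  expect_error(fitch_parsimony_score(t4, deg_msa(c(Z = "A", B = "A",
                                                   C = "A", D = "A"))),
               "match")
})

test_that("log-likelihood matches closed forms and enumeration", {
  m <- wag_model()
  t0 <- read_newick("(a:0,b:0);")
  one <- deg_msa(c(a = "A", b = "A"))
  expect_equal(log_likelihood(t0, one, m), log(m$freqs[["A"]]),
               tolerance = 1e-10)

  t50 <- read_newick("(a:25,b:25);")
  two <- deg_msa(c(a = "A", b = "R"))
  expect_equal(log_likelihood(t50, two, m),
               log(m$freqs[["A"]]) + log(m$freqs[["R"]]),
               tolerance = 1e-6)

  skip_if_not_installed("Matrix")
  set.seed(23)
  for (i in 1:3) {
    tr <- read_newick(sprintf("((A:%.2f,B:%.2f):%.2f,(C:%.2f,D:%.2f):%.2f);",
                              runif(1, .05, .6), runif(1, .05, .6),
                              runif(1, .05, .4), runif(1, .05, .6),
                              runif(1, .05, .6), runif(1, .05, .4)))
    M <- matrix(sample(c("A", "R", "N", "D", "S", "H"), 8, replace = TRUE),
                4, 2, dimnames = list(LETTERS[1:4], NULL))
    if (i == 3) M[2, 1] <- "-"            # exercise gap marginalisation
    msa <- structure(M, class = "deg_msa")
    expect_equal(log_likelihood(tr, msa, m), brute_loglik(tr, msa, m),
                 tolerance = 1e-9, info = paste("case", i))
  }
})

test_that("log-likelihood is invariant under re-rooting", {
  m <- wag_model()
  set.seed(3)
  tr <- ape::rtree(6)
  tr$tip.label <- paste0("t", 1:6)
  fam_tree <- ape::unroot(tr)
  M <- matrix(sample(c("A", "R", "N", "D", "S"), 6 * 20, replace = TRUE),
              6, 20, dimnames = list(tr$tip.label, NULL))
  msa <- structure(M, class = "deg_msa")
  base <- log_likelihood(fam_tree, msa, m)
  for (og in c("t1", "t4")) {
    rr <- ape::root(fam_tree, outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(rr, msa, m), base, tolerance = 1e-9)
  }
})

test_that("branch-length optimisation is monotone and hits bounds", {
  m <- wag_model()
  t1 <- read_newick("(a:0.5,b:0.5);")
  same <- deg_msa(c(a = "ARNDARNDAR", b = "ARNDARNDAR"))
  o1 <- optimize_branch_lengths(t1, same, m)
  expect_lte(sum(o1$edge.length), 1e-6)    # driven to the lower bound

  # every site substituted by a rarely-exchanged pair: the likelihood
  # increases monotonically in t and the estimate saturates at the bound
  diff <- deg_msa(c(a = "GGGGGGGGGG", b = "IIIIIIIIII"))
  o2 <- optimize_branch_lengths(t1, diff, m)
  expect_gte(sum(o2$edge.length), 20)

  set.seed(13)
  tr <- ape::rtree(5)
  tr$tip.label <- paste0("t", 1:5)
  M <- matrix(sample(c("A", "R", "N", "D"), 5 * 30, replace = TRUE), 5, 30,
              dimnames = list(tr$tip.label, NULL))
  msa <- structure(M, class = "deg_msa")
  o3 <- optimize_branch_lengths(tr, msa, m)
  expect_gte(attr(o3, "loglik"), log_likelihood(tr, msa, m))
  expect_error(optimize_branch_lengths(
    read_newick("(a:-1,b:1);"), same, m), "negative")
})

test_that("NNI search recovers the generating topology", {
  m <- wag_model()
  truth <- read_newick("((A:0.1,B:0.1):0.15,(C:0.1,D:0.1):0.15);")
  set.seed(8)
  sim <- evolve_sequences(truth, m, length = 500, seed = 8)
  msa <- msa_from_sim(sim)
  wrong <- read_newick("((A:0.1,C:0.1):0.15,(B:0.1,D:0.1):0.15);")
  found <- nni_search(wrong, msa, m)
  expect_equal(rf_distance(found, truth), 0L)
  expect_gte(attr(found, "loglik"), log_likelihood(wrong, msa, m))

  # already-optimal tree stays put: both NNI alternatives score worse
  again <- nni_search(found, msa, m)
  expect_equal(rf_distance(again, found), 0L)

  # three leaves: no internal edge, returned unchanged
  t3 <- read_newick("(a:1,b:1,c:1);")
  msa3 <- deg_msa(c(a = "ARND", b = "ARND", c = "ARND"))
  n3 <- nni_search(t3, msa3, m)
  expect_setequal(n3$tip.label, t3$tip.label)
  expect_equal(n3$Nnode, 1L)
})

test_that("full ML inference improves on its NJ start", {
  m <- wag_model()
  set.seed(4)
  M <- matrix(sample(c("A", "R", "N", "D", "S"), 3 * 40, replace = TRUE),
              3, 40, dimnames = list(c("a", "b", "c"), NULL))
  msa3 <- structure(M, class = "deg_msa")
  t3 <- infer_ml_tree(msa3, m, seed = 1)
  expect_setequal(t3$tip.label, c("a", "b", "c"))

  fam <- simulate_family(simulation_config(
    n_species = 6, duplication_rate = 0, loss_rate = 0,
    inactivation_fraction = 0, include_outgroup = FALSE, seed = 1))
  msa6 <- msa_from_sim(fam$sequences)
  inferred <- infer_ml_tree(msa6, m, seed = 1)
  species_topo <- fam$species_tree
  species_topo$tip.label <- paste0(species_topo$tip.label, "_g1")
  expect_equal(rf_distance(inferred, species_topo), 0L)

  start <- neighbor_joining(pairwise_distances(msa6))
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  opt_start <- optimize_branch_lengths(start, msa6, m)
  expect_gte(attr(inferred, "loglik"), attr(opt_start, "loglik") - 1e-6)
})

test_that("bootstrap supports are deterministic, bounded and saturate", {
  m <- wag_model()
  fam <- simulate_family(simulation_config(
    n_species = 6, duplication_rate = 0, loss_rate = 0,
    inactivation_fraction = 0, include_outgroup = FALSE, seed = 1))
  msa6 <- msa_from_sim(fam$sequences)

  b1 <- bootstrap_supports(msa6, m, bootstrap_config(25, seed = 2))
  b2 <- bootstrap_supports(msa6, m, bootstrap_config(25, seed = 2))
  expect_identical(write_newick(b1), write_newick(b2))

  sup <- attr(b1, "split_support")
  expect_true(all(sup >= 0 & sup <= 100))

  # single-column alignment: degenerate but well-defined
  one_col <- structure(unclass(msa6)[, 1, drop = FALSE], class = "deg_msa")
  b3 <- suppressWarnings(bootstrap_supports(one_col, m,
                                            bootstrap_config(3, seed = 1)))
  expect_s3_class(b3, "phylo")
  expect_true(all(attr(b3, "split_support") >= 0 &
                    attr(b3, "split_support") <= 100))
})

test_that("Robinson-Foulds distances count unshared bipartitions", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t2, t1), rf_distance(t1, t2))
  t3 <- read_newick("((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(rf_distance(t1, t3), "leaf sets")
})

test_that("Newick I/O preserves supports, lengths and rejects bad input", {
  tr <- read_newick("((A:1,B:2)90:1,C:3);")
  expect_true("90" %in% tr$node.label)
  rt <- read_newick(write_newick(tr))
  expect_equal(rt$node.label, tr$node.label)
  expect_equal(rt$edge.length, tr$edge.length)
  expect_equal(rt$tip.label, tr$tip.label)
  expect_error(read_newick("((A,B);"), "parse")
  expect_error(read_newick("((A:1,A:2):1,C:3);"), "duplicate")
})

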