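# A handcrafted study: two reference anchors (Deg1, Deg5), a green-alga
# pair inside the Deg1 clade, a poplar member joining the Deg1 clade one
# node higher, a moss Deg5 ortholog, an unanchored but well-supported
# poplar pair, and a two-member outgroup.  The crown has weak support (60)
# so leaves outside every anchored clade become "like" members.
toy_tree <- function() read_newick(paste0(
  "((Sy1:0.1,Sy2:0.1)60:0.5,",
  "(((At1:0.1,(Cr1:0.05,Cr2:0.06)95:0.05)95:0.1,PtA:0.3)95:0.1,",
  "((At5:0.1,Pp5:0.1)95:0.1,(Lk1:0.2,Lk2:0.2)95:0.3)60:0.1)60:0.5);"))

toy_tree_catalog <- function(not_family = character(0)) {
  ids <- c("At1", "At5", "Cr1", "Cr2", "PtA", "Pp5", "Lk1", "Lk2",
           "Sy1", "Sy2")
  toy_catalog(data.frame(
    id = ids,
    species = c("At", "At", "Cr", "Cr", "Pt", "Pp", "Pt", "Pt",
                "Syn", "Syn"),
    anchor_name = c("Deg1", "Deg5", rep("", 8)),
    architecture = c("PD-PDZ", "PD", "PD-PDZ", "PD-PDZ", "PD-PDZ", "PD",
                     "PD_ia-PDZ", "PD_ia-PDZ", "PD-PDZ", "PD-PDZ"),
    not_family = ids %in% not_family))
}

test_that("outgroup rooting splits the stem and keeps supports", {
  u <- ape::unroot(toy_tree())
  rooted <- root_with_outgroup(u, c("Sy1", "Sy2"))
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  sides <- lapply(kids, function(k)
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label)
  expect_true(any(vapply(sides, setequal, TRUE, c("Sy1", "Sy2"))))
  # stem split evenly across the two root edges
  re <- rooted$edge.length[rooted$edge[, 1] == ape::Ntip(rooted) + 1L]
  expect_equal(re[1], re[2])
  # supports survive re-rooting, attached to the same bipartitions
  cl <- supported_clades(rooted, 90)
  expect_true(any(vapply(cl, setequal, TRUE, c("At1", "Cr1", "Cr2"))))
  expect_true(any(vapply(cl, setequal, TRUE, c("At5", "Pp5"))))

  expect_error(root_with_outgroup(u, character(0)), "empty")
  expect_error(root_with_outgroup(u, c("Sy1", "nope")), "absent")
})

test_that("non-monophyletic outgroups root on the best-separating edge", {
  u <- read_newick("((O1:1,A:1):1,(O2:1,B:1):1,C:1);")
  expect_warning(rooted <- root_with_outgroup(u, c("O1", "O2")),
                 "not monophyletic")
  # exhaustive edge scan: separating O1 alone scores 4 correctly placed
  # leaves (O1 | A,B,C), the best achievable on this tree
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  sides <- lapply(kids, function(k)
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label)
  expect_true(any(vapply(sides, identical, TRUE, "O1")))
})

test_that("supported clades respect the strict threshold", {
  t4 <- read_newick("((A:1,B:1)100:1,(C:1,D:1)100:1);")
  cl <- supported_clades(t4, 70)
  expect_length(cl, 2L)
  expect_length(supported_clades(t4, 100), 0L)

  tr <- toy_tree()
  got <- supported_clades(tr, 90)
  sets <- lapply(got, sort)
  manual <- list(c("At1", "Cr1", "Cr2", "PtA"), c("At1", "Cr1", "Cr2"),
                 c("Cr1", "Cr2"), c("At5", "Pp5"), c("Lk1", "Lk2"))
  expect_setequal(lapply(sets, paste, collapse = "|"),
                  lapply(lapply(manual, sort), paste, collapse = "|"))
  # sizes are non-increasing
  expect_true(all(diff(vapply(got, length, 0L)) <= 0))

  bare <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(supported_clades(bare, 70), "support")
})

test_that("flagged and unclustered records are excluded for -like naming", {
  tr <- toy_tree()
  ex0 <- exclude_distant_relatives(tr, toy_tree_catalog(),
                                   nomenclature_config())
  expect_equal(nrow(ex0$excluded), 0L)

  ex1 <- exclude_distant_relatives(tr, toy_tree_catalog(not_family = "Lk2"),
                                   nomenclature_config())
  expect_equal(ex1$excluded$id, "Lk2")
  expect_equal(ex1$excluded$reason, "NOT_FAMILY_FLAG")
  expect_false("Lk2" %in% ex1$retained)

  # a basal loner in no supported clade is a distant relative
  tr2 <- read_newick(paste0(
    "((Sy1:0.1,Sy2:0.1)99:0.5,",
    "((At1:0.1,Cr1:0.1)95:0.2,Zz1:0.6)60:0.3);"))
  cat2 <- toy_catalog(data.frame(
    id = c("At1", "Cr1", "Zz1", "Sy1", "Sy2"),
    species = c("At", "Cr", "Cr", "Syn", "Syn"),
    anchor_name = c("Deg1", "", "", "", "")))
  ex2 <- exclude_distant_relatives(tr2, cat2, nomenclature_config())
  expect_equal(ex2$excluded$id, "Zz1")
  expect_equal(ex2$excluded$reason, "DISTANT_RELATIVE")

  # threshold 100: no supported clades remain, every non-outgroup leaf
  # drops out (documented degenerate behaviour)
  ex3 <- exclude_distant_relatives(
    tr, toy_tree_catalog(), nomenclature_config(assignment_threshold = 100))
  expect_setequal(ex3$excluded$id,
                  c("At1", "At5", "Cr1", "Cr2", "PtA", "Pp5", "Lk1", "Lk2"))
})

test_that("ortholog groups are anchored, liked and group-liked correctly", {
  tr <- toy_tree()
  cat <- toy_tree_catalog()
  g <- assign_ortholog_groups(tr, cat)
  asn <- g$assignment
  rownames(asn) <- asn$id
  expect_equal(asn["Cr1", "group"], "Deg1")
  expect_equal(asn["Cr2", "group"], "Deg1")
  expect_equal(asn["Cr1", "status"], "anchored")
  expect_equal(asn["PtA", "group"], "Deg1")     # one node higher, one anchor
  expect_equal(asn["Pp5", "group"], "Deg5")
  expect_equal(asn["Lk1", "status"], "like")
  expect_equal(asn["Lk1", "group"], asn["Lk2", "group"])
  expect_match(asn["Lk1", "group"], "^Deg-like 1$")
  # outgroup tips are not assigned
  expect_false(any(c("Sy1", "Sy2") %in% asn$id))
  # total, unique assignment of every retained leaf
  expect_setequal(asn$id, setdiff(tr$tip.label, c("Sy1", "Sy2")))
  expect_true(all(nzchar(asn$group)))

  # ambiguous minimal clade (two anchor names) gives group_like status
  tr2 <- read_newick(paste0(
    "((Sy1:0.1,Sy2:0.1)99:0.5,",
    "((At1:0.1,At5:0.12)95:0.2,PpG:0.4)95:0.3);"))
  cat2 <- toy_catalog(data.frame(
    id = c("At1", "At5", "PpG", "Sy1", "Sy2"),
    species = c("At", "At", "Pp", "Syn", "Syn"),
    anchor_name = c("Deg1", "Deg5", "", "", "")))
  g2 <- assign_ortholog_groups(tr2, cat2)
  asn2 <- g2$assignment
  expect_equal(asn2$status[asn2$id == "PpG"], "group_like")
  expect_equal(asn2$group[asn2$id == "PpG"], "Deg1")   # nearest anchor

  expect_error(assign_ortholog_groups(
    tr2, toy_catalog(data.frame(id = c("PpG"), species = "Pp",
                                anchor_name = ""))),
    "missing from catalog|anchors")
})

test_that("raising the threshold never turns like into anchored", {
  tr <- toy_tree()
  cat <- toy_tree_catalog()
  lo <- assign_ortholog_groups(tr, cat, nomenclature_config())
  hi <- assign_ortholog_groups(tr, cat,
                               nomenclature_config(assignment_threshold = 96))
  status_of <- function(g) setNames(g$assignment$status, g$assignment$id)
  slo <- status_of(lo); shi <- status_of(hi)
  # anchored at the stricter threshold implies anchored at the looser one
  expect_true(all(slo[names(shi)[shi == "anchored"]] == "anchored"))
  # and a like member never becomes anchored as the threshold rises
  expect_true(all(shi[names(slo)[slo == "like"]] == "like"))
})

test_that("proposed names follow the suffix and prefix rules", {
  tr <- toy_tree()
  cat <- toy_tree_catalog()
  g <- assign_ortholog_groups(tr, cat)
  nm <- propose_names(g, cat)
  expect_equal(nm[["At1"]], "AtDeg1")     # reference keeps its name
  expect_equal(nm[["At5"]], "AtDeg5")
  expect_equal(nm[["Pp5"]], "PpDeg5")     # single member: no suffix
  expect_equal(nm[["PtA"]], "PtDeg1")
  # suffixes ordered by patristic distance to the anchor
  expect_equal(nm[["Cr1"]], "CrDeg1.1")
  expect_equal(nm[["Cr2"]], "CrDeg1.2")
  expect_setequal(unname(nm[c("Lk1", "Lk2")]),
                  c("PtDeg-like 1.1", "PtDeg-like 1.2"))
  expect_false(anyDuplicated(nm) > 0)

  # group-like member names carry the suffix
  tr2 <- read_newick(paste0(
    "((Sy1:0.1,Sy2:0.1)99:0.5,",
    "((At1:0.1,At5:0.12)95:0.2,PpG:0.4)95:0.3);"))
  cat2 <- toy_catalog(data.frame(
    id = c("At1", "At5", "PpG", "Sy1", "Sy2"),
    species = c("At", "At", "Pp", "Syn", "Syn"),
    anchor_name = c("Deg1", "Deg5", "", "", "")))
  nm2 <- propose_names(assign_ortholog_groups(tr2, cat2), cat2)
  expect_equal(nm2[["PpG"]], "PpDeg1-group-like")
})

test_that("architecture concordance reports majorities and discord", {
  tr <- toy_tree()
  cat <- toy_tree_catalog()
  g <- assign_ortholog_groups(tr, cat)
  rep <- architecture_concordance(g, cat)
  deg1 <- rep[rep$group == "Deg1", ]
  expect_equal(deg1$majority_architecture, "PD-PDZ")
  expect_equal(deg1$discordant, "")

  # a fusion member is flagged discordant, never fatal
  cat$records$architecture[cat$records$id == "Cr2"] <-
    "PD-betaglycanhydrolase"
  rep2 <- architecture_concordance(g, cat)
  expect_equal(rep2$discordant[rep2$group == "Deg1"], "Cr2")

  # a member without an architecture is unassessed
  cat$records$architecture[cat$records$id == "Cr1"] <- ""
  rep3 <- architecture_concordance(g, cat)
  expect_match(rep3$unassessed[rep3$group == "Deg1"], "Cr1")
})

test_that("clade labels annotate groups by configured sets", {
  tr <- toy_tree()
  g <- assign_ortholog_groups(tr, toy_tree_catalog())
  lab <- label_clades(g)
  expect_equal(lab$clade[lab$group == "Deg1"], "I A")
  expect_equal(lab$clade[lab$group == "Deg-like 1"], "")
})
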