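test_that("JC distances follow the closed form with an Inf sentinel", {
  a <- rep("a", 100); g <- rep("g", 100)
  aln <- rbind(s1 = a, s2 = a)
  expect_equal(unname(jc_distance(aln)["s1", "s2"]), 0)

  # p = 0.02 over 100 sites
  s3 <- a; s3[1:2] <- "g"
  d <- jc_distance(rbind(s1 = a, s3 = s3))
  expect_equal(unname(d["s1", "s3"]), -0.75 * log(1 - 4 / 3 * 0.02),
               tolerance = 1e-9)
  expect_equal(unname(d["s1", "s3"]), 0.02027, tolerance = 1e-4)

  # p = 0.75 saturates the formula domain
  s4 <- c(rep("g", 75), rep("a", 25))
  d2 <- jc_distance(rbind(s1 = a, s4 = s4))
  expect_identical(unname(d2["s1", "s4"]), Inf)

  # gaps skipped pairwise; no shared columns is an error
  s5 <- c(rep("-", 50), rep("a", 50)); s6 <- c(rep("a", 50), rep("-", 50))
  expect_error(jc_distance(rbind(s5 = s5, s6 = s6)), "comparable")
})

test_that("neighbor joining recovers additive trees and validates input", {
  # 3 taxa: unique topology, branch lengths from the three-point formulas
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))

  # additive 4-taxon matrix with split AB|CD
  D4 <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4,
               dimnames = list(c("A", "B", "C", "D"),
                               c("A", "B", "C", "D")))
  t4 <- neighbor_joining(D4)
  expect_true(ape::is.monophyletic(t4, c("A", "B")) ||
                ape::is.monophyletic(t4, c("C", "D")))

  # taxon order invariance of the unrooted topology
  perm <- c("C", "A", "D", "B")
  t4p <- neighbor_joining(D4[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(t4p)),
               0, ignore_attr = TRUE)

  D4bad <- D4; D4bad[1, 2] <- D4bad[2, 1] <- NaN
  expect_error(neighbor_joining(D4bad), "NaN|finite")
  expect_error(neighbor_joining(D4[, 1:3]), "square")
})

test_that("outgroup rooting requires monophyly and places the root", {
  tr <- ape::read.tree(text = "((A_X:1,B_X:1):1,(C_Y:1,OUT_A:1):1);")
  rooted <- root_with_outgroup(tr, "OUT_A")
  expect_true(ape::is.rooted(rooted))

  # a 2-leaf outgroup cherry is a valid root
  tr2 <- ape::read.tree(
    text = "((A_X:1,B_X:1):1,((O1_A:1,O2_A:1):1,C_Y:1):1);")
  expect_true(ape::is.rooted(root_with_outgroup(tr2, c("O1_A", "O2_A"))))

  # outgroup split across the tree is refused
  tr3 <- ape::read.tree(text = "((O1_A:1,B_X:1):1,(O2_A:1,C_Y:1):1);")
  expect_error(root_with_outgroup(tr3, c("O1_A", "O2_A")),
               "monophyletic")
  expect_error(root_with_outgroup(tr, "missing_leaf"), "not in tree")
})

test_that("topology classification matches the three turnover signatures", {
  # neo-Y from X: focal species' Y is the earliest-branching ingroup lineage
  neo <- ape::read.tree(text = paste0(
    "(((((Sdun_X,Scha_X),(Sdun_Y,Scha_Y)),Smes_X),Smes_Y),Out_A);"))
  cls <- classify_gametolog_topology(neo)
  expect_equal(cls$class, "NEO_FROM_X")
  expect_equal(cls$focal_species, "Smes")

  # gametolog clustering across XY and ZW species (X with W, Y with Z)
  gam <- ape::read.tree(text = paste0(
    "((((Tri_X,Arb_X),(Pol_W,Pur_W)),((Tri_Y,Arb_Y),(Pol_Z,Pur_Z))),",
    "Out_A);"))
  expect_equal(classify_gametolog_topology(gam)$class,
               "GAMETOLOG_CLUSTERING")

  # species clustering: gametologs are sisters within each species
  spc <- ape::read.tree(text = "(((A_X,A_Y),(B_X,B_Y)),Out_A);")
  expect_equal(classify_gametolog_topology(spc)$class,
               "SPECIES_CLUSTERING")

  # an inconsistent arrangement stays unresolved
  unr <- ape::read.tree(text = "(((A_X,B_Y),(A_Y,B_X)),Out_A);")
  expect_equal(classify_gametolog_topology(unr)$class, "UNRESOLVED")

  # invariance to leaf order and branch-length rescaling
  neo2 <- ape::read.tree(text = paste0(
    "((Smes_Y:9,(Smes_X:9,((Scha_Y:2,Sdun_Y:2):1,(Scha_X:2,Sdun_X:2):1)",
    ":4):3):2,Out_A:20);"))
  cls2 <- classify_gametolog_topology(neo2)
  expect_equal(cls2$class, "NEO_FROM_X")
  expect_equal(cls2$focal_species, "Smes")

  # malformed input: a species with a duplicated haplotype leaf
  dup <- ape::read.tree(text = "(((A_X,A_X2),(A_Y,B_X)),Out_A);")
  expect_error(classify_gametolog_topology(
    labeled_tree(dup, data.frame(
      leaf = c("A_X", "A_X2", "A_Y", "B_X", "Out_A"),
      species = c("A", "A", "A", "B", "Out"),
      haplotype = c("X", "X", "Y", "X", "A")))),
    "exactly one")
})

test_that("tallies count classes and apply the majority tie rule", {
  neo <- ape::read.tree(text = paste0(
    "(((((Sdun_X,Scha_X),(Sdun_Y,Scha_Y)),Smes_X),Smes_Y),Out_A);"))
  unr <- ape::read.tree(text = paste0(
    "((((Sdun_X,Scha_Y),(Sdun_Y,Scha_X)),(Smes_X,Smes_Y)),Out_A);"))
  trees <- c(replicate(7, neo, simplify = FALSE),
             replicate(13, unr, simplify = FALSE))
  names(trees) <- sprintf("SCO%02d", 1:20)
  rep <- tally_topologies(trees)
  expect_equal(unname(rep$counts["NEO_FROM_X"]), 7L)
  expect_equal(unname(rep$counts["UNRESOLVED"]), 13L)
  expect_equal(rep$majority, "NEO_FROM_X")
  expect_setequal(rep$sco_by_class$NEO_FROM_X, sprintf("SCO%02d", 1:7))

  # all trees identical -> a single class
  same <- tally_topologies(replicate(5, neo, simplify = FALSE))
  expect_equal(unname(same$counts["NEO_FROM_X"]), 5L)

  # 50/50 split between resolved classes -> UNRESOLVED majority
  spc <- ape::read.tree(text = "(((A_X,A_Y),(B_X,B_Y)),Out_A);")
  gam <- ape::read.tree(text = "(((A_X,B_X),(A_Y,B_Y)),Out_A);")
  tie <- tally_topologies(list(a = spc, b = gam))
  expect_equal(tie$majority, "UNRESOLVED")
})

test_that("simulated scenarios are recovered through the full tree path", {
  species <- c("Smes", "Sdun", "Scha", "Satr")
  for (scen in c("GAMETOLOG_CLUSTERING", "SPECIES_CLUSTERING",
                 "NEO_FROM_X")) {
    sim <- simulate_gametolog_sequences(scen, species,
                                        mutation_scale = 0.05,
                                        seq_length = 2000, seed = 61)
    # classification of the generating tree itself is always exact
    true_cls <- classify_gametolog_topology(sim$tree)
    expect_equal(true_cls$class, scen)
    # and the NJ tree built from the evolved sequences recovers it
    d <- jc_distance(sim$alignment)
    nj_tree <- neighbor_joining(d)
    rooted <- root_with_outgroup(nj_tree, "Ipoly_A")
    cls <- classify_gametolog_topology(rooted)
    expect_equal(cls$class, scen)
    if (scen == "NEO_FROM_X") expect_equal(cls$focal_species, "Smes")
  }
  # zero mutation scale: all sequences identical
  flat <- simulate_gametolog_sequences("SPECIES_CLUSTERING", c("A", "B"),
                                       mutation_scale = 0, seed = 62)
  expect_equal(length(unique(apply(
    as.character(flat$alignment), 1, paste, collapse = ""))), 1L)
  expect_error(simulate_gametolog_sequences("NEO_FROM_X", c("A", "B")),
               "at least 3")
})
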