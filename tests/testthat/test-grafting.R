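fagales_tree <- function() read_newick("((Qrobur:3,Fsylv:3):2,Pinus:5);")

fagales_tax <- function() {
  tibble::tibble(
    species = c("Qrobur", "Fsylv", "Pinus", "Quercus_ilex", "Qsuber",
                "Ulmus_minor"),
    genus = c("Quercus", "Fagus", "Pinus", "Quercus", "Quercus", "Ulmus"),
    family = c("Fagaceae", "Fagaceae", "Pinaceae", "Fagaceae", "Fagaceae",
               "Ulmaceae")
  )
}

test_that("nearest relative: single congener, congener MRCA, unplaceable", {
  tr <- fagales_tree()
  tax <- fagales_tax()
  hit <- find_nearest_relative(tr, "Quercus_ilex", tax)
  expect_equal(hit$rank, "genus")
  expect_equal(hit$attachment_label, "Qrobur")

  tr2 <- graft_species(tr, "Qsuber", tax, seed = 1)$tree
  hit2 <- find_nearest_relative(tr2, "Quercus_ilex", tax)
  expect_equal(hit2$rank, "genus")
  expect_match(hit2$attachment_label, "mrca")
  clade <- ape::extract.clade(tr2, hit2$attachment_node)$tip.label
  expect_true(all(c("Qrobur", "Qsuber") %in% clade))

  # family rank engages when no congener exists
  hit3 <- find_nearest_relative(tr, "Fsylv2", dplyr::bind_rows(
    tax, tibble::tibble(species = "Fsylv2", genus = "NotInTree",
                        family = "Fagaceae")))
  expect_equal(hit3$rank, "family")

  expect_error(find_nearest_relative(tr, "Ulmus_minor", tax),
               class = "littertraits_unplaceable")
})

test_that("insertion adds a sibling with the attachment's pendant length", {
  tr <- fagales_tree()
  out <- insert_species(tr, "Quercus_ilex", match("Qrobur", tr$tip.label))
  d <- root_to_tip_depths(out)
  expect_equal(d$depth[d$label == "Quercus_ilex"], 5)  # 2 + 3, as Qrobur
  # parent of Qrobur now has three children (polytomy, resolved later)
  par <- out$edge[out$edge[, 2] == match("Qrobur", out$tip.label), 1]
  expect_equal(sum(out$edge[, 1] == par), 3L)
  # pre-existing leaf depths untouched
  for (sp in c("Qrobur", "Fsylv", "Pinus")) {
    expect_equal(d$depth[d$label == sp],
                 c(Qrobur = 5, Fsylv = 5, Pinus = 5)[[sp]])
  }
  expect_warning(ins2 <- insert_species(out, "Quercus_ilex", 1L),
                 "already in tree")
  expect_equal(sort(ins2$tip.label), sort(out$tip.label))
})

test_that("polytomy resolution applies the half-shortest-child rule", {
  tr <- read_newick(star_newick(c(2, 4, 6), c("A", "B", "C")))
  res <- resolve_polytomies(tr, seed = 1)
  expect_true(ape::is.binary(res))
  # new internal edge length is half the shortest child branch
  tips <- match(c("A", "B", "C"), res$tip.label)
  internal <- setdiff(res$edge[, 2], tips)
  expect_equal(res$edge.length[match(internal, res$edge[, 2])], 1)
  # all leaf depths conserved
  d <- root_to_tip_depths(res)
  expect_equal(setNames(d$depth, d$label)[c("A", "B", "C")],
               c(A = 2, B = 4, C = 6))
  # the untouched child keeps its original branch length
  grouped <- res$edge[res$edge[, 1] == internal, 2]
  lone <- setdiff(tips, grouped)
  expect_equal(res$edge.length[match(lone, res$edge[, 2])],
               c(2, 4, 6)[match(res$tip.label[lone], c("A", "B", "C"))])
})

test_that("a zero-length shortest child yields a zero-length new edge", {
  tr <- read_newick(star_newick(c(0, 4, 6), c("A", "B", "C")))
  res <- resolve_polytomies(tr, seed = 3)
  expect_true(ape::is.binary(res))
  d <- root_to_tip_depths(res)
  expect_equal(setNames(d$depth, d$label)[c("A", "B", "C")],
               c(A = 0, B = 4, C = 6))
  expect_true(all(res$edge.length >= 0))
})

test_that("a 5-child polytomy resolves in 3 steps with depths conserved", {
  lens <- c(1.5, 2, 3.5, 5, 8)
  tr <- read_newick(star_newick(lens))
  res <- resolve_polytomies(tr, seed = 11)
  expect_true(ape::is.binary(res))
  expect_equal(res$Nnode, 4L)  # 1 original + 3 new internal nodes
  d <- root_to_tip_depths(res)
  expect_equal(setNames(d$depth, d$label)[paste0("t", 1:5)],
               setNames(lens, paste0("t", 1:5)))
})

test_that("distance conservation holds on fuzzed polytomies", {
  for (seed in 1:50) {
    lens <- withr::with_seed(seed, stats::runif(sample(3:10, 1), 0, 10))
    tr <- read_newick(star_newick(round(lens, 6)))
    before <- root_to_tip_depths(tr)
    res <- resolve_polytomies(tr, seed = seed + 1000)
    after <- root_to_tip_depths(res)
    after <- after$depth[match(before$label, after$label)]
    expect_lt(max(abs(after - before$depth) / pmax(before$depth, 1e-9)), 1e-9)
    expect_true(ape::is.binary(res))
  }
})

test_that("graft_species is deterministic, binary, monotone and alphabetical", {
  ys <- simulate_yule_tree(80, seed = 21)
  drop <- withr::with_seed(4, sample(ys$tree$tip.label, 25))
  backbone <- ape::drop.tip(ys$tree, drop)
  g1 <- graft_species(backbone, drop, ys$taxonomy, seed = 5)
  g2 <- graft_species(backbone, drop, ys$taxonomy, seed = 5)
  expect_identical(write_newick(g1$tree), write_newick(g2$tree))
  g3 <- graft_species(backbone, drop, ys$taxonomy, seed = 6)
  expect_false(identical(write_newick(g1$tree), write_newick(g3$tree)))

  expect_true(ape::is.binary(g1$tree))
  expect_true(all(backbone$tip.label %in% g1$tree$tip.label))
  expect_identical(g1$report$species, sort(g1$report$species))
  expect_true(all(drop %in% g1$report$species))

  # backbone leaf depths unchanged by grafting
  before <- root_to_tip_depths(backbone)
  after <- root_to_tip_depths(g1$tree)
  after <- after$depth[match(before$label, after$label)]
  expect_lt(max(abs(after - before$depth) / before$depth), 1e-9)

  # ultrametric backbone stays ultrametric after grafting + resolution
  expect_true(is_ultrametric(g1$tree, tol = 1e-6))

  # single-relative placements: pendant equals the attachment's pendant
  placed <- g1$report[g1$report$status == "placed" &
                        !grepl("mrca", g1$report$attachment_label), ]
  for (i in seq_len(nrow(placed))) {
    att_depth <- root_to_tip_depths(g1$tree)
    expect_true(placed$pendant_length[i] >= 0)
  }
})

test_that("graft_species handles empty lists, re-inserts and unplaceables", {
  tr <- read_newick("((A_x:1,B_x:1,C_x:1):1,D_x:2);")
  tax <- tibble::tibble(species = c("A_x", "B_x", "C_x", "D_x", "Zed_q"),
                        genus = c("A", "B", "C", "D", "Zed"),
                        family = c("F1", "F1", "F1", "F2", "F3"))
  g <- graft_species(tr, character(0), tax, seed = 1)
  expect_true(ape::is.binary(g$tree))  # pre-existing polytomy resolved
  expect_equal(nrow(g$report), 0L)

  expect_warning(g2 <- graft_species(tr, "A_x", tax, seed = 1),
                 "already in tree")
  expect_equal(g2$report$status, "already_present")

  g3 <- graft_species(tr, "Zed_q", tax, seed = 1)
  expect_equal(g3$report$status, "unplaceable")
  expect_false("Zed_q" %in% g3$tree$tip.label)
})
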