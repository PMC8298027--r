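test_that("pairwise divergence matches the allele-sharing definition", {
  same <- geno_matrix(matrix(c(0, 0, 1, 1, 2, 2), 2, 3, byrow = FALSE))
  expect_equal(pairwise_divergence(same)[1, 2], 0)

  opp <- geno_matrix(matrix(c(0, 2, 0, 2, 0, 2), 2, 3))
  expect_equal(pairwise_divergence(opp)[1, 2], 1)

  # hom-het pairs count half
  expect_equal(pairwise_divergence(geno_matrix(rbind(c(0, 0), c(1, 1))))[1, 2],
               0.5)

  expect_error(pairwise_divergence(impute_mean(
    geno_matrix(rbind(c(0, NA), c(1, 2))))), "un-imputed")
})

test_that("divergence equals a brute-force double loop with missing data", {
  set.seed(51)
  calls <- matrix(sample(c(0, 1, 2, NA), 6 * 30, TRUE,
                         prob = c(0.35, 0.3, 0.25, 0.1)), 6, 30)
  calls[, 1] <- 1  # keep all pairs sharing at least one marker
  gm <- geno_matrix(calls)
  D <- pairwise_divergence(gm)
  for (i in 1:5) for (j in (i + 1):6) {
    sh <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    expect_equal(D[i, j], mean(abs(calls[i, sh] - calls[j, sh])) / 2)
  }
  expect_equal(unname(diag(D)), rep(0, 6))

  # invariance to marker and sample order
  pm <- sample(30); ps <- sample(6)
  D2 <- pairwise_divergence(geno_matrix(calls[ps, pm]))
  expect_equal(unname(D2), unname(D[ps, ps]))

  # count scale sums the per-site differences over shared markers
  Dc <- pairwise_divergence(gm, scale = "count")
  sh12 <- !is.na(calls[1, ]) & !is.na(calls[2, ])
  expect_equal(Dc[1, 2], sum(abs(calls[1, sh12] - calls[2, sh12])) / 2)

  # a pair with no shared markers is an error
  bad <- geno_matrix(rbind(a = c(0, NA), b = c(NA, 2)))
  expect_error(pairwise_divergence(bad), "share no")
})

test_that("nucleotide diversity is the mean pairwise divergence", {
  const <- geno_matrix(matrix(1, 4, 10))
  expect_equal(nucleotide_diversity(const), 0)

  two <- geno_matrix(rbind(a = c(0, 1, 2), b = c(2, 1, 2)))
  expect_equal(nucleotide_diversity(two),
               pairwise_divergence(two)["a", "b"])

  set.seed(52)
  calls <- matrix(sample(0:2, 5 * 20, TRUE), 5, 20)
  gm <- geno_matrix(calls)
  D <- pairwise_divergence(gm)
  expect_equal(nucleotide_diversity(gm), mean(D[lower.tri(D)]))

  # per-tag-base rescaling divides by the tag length
  expect_equal(nucleotide_diversity(gm, tag_length = 69),
               nucleotide_diversity(gm) / 69)
  expect_error(nucleotide_diversity(gm, subset = "S1"), "at least 2")
})

test_that("neighbor joining recovers additive trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(D)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, LETTERS[1:4])
  # path lengths between tips reproduce the input matrix exactly
  patristic <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(patristic, D, tolerance = 1e-9)
  # the AB | CD split is an edge of the tree
  splits <- ape::prop.part(tree)
  expect_true(all(tree$edge.length >= 0))

  # 3 taxa: three-point formulas
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)

  expect_error(neighbor_joining(D3[1:2, 1:2]), "at least 3")
  D_bad <- D3; D_bad[1, 2] <- D_bad[2, 1] <- Inf
  expect_error(neighbor_joining(D_bad), "non-finite")
})

test_that("clear pairs join first on near-ultrametric input", {
  # two tight pairs (A,B) and (C,D), far apart
  D <- matrix(c(0, 1, 8, 8,
                1, 0, 8, 8,
                8, 8, 0, 1,
                8, 8, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(D)
  # check AB and CD are cherries: each pair shares a parent node
  parent_of <- function(tip) tree$edge[tree$edge[, 2] ==
                                       which(tree$tip.label == tip), 1]
  expect_equal(parent_of("A"), parent_of("B"))
  expect_equal(parent_of("C"), parent_of("D"))
})

test_that("F_ST partitions diversity between clusters", {
  expect_equal(fst_from_diversity(0.2, c(0.2, 0.2), c(5, 5)), 0)
  expect_equal(fst_from_diversity(0.3, c(0, 0), c(4, 4)), 1)
  expect_warning(f0 <- fst_from_diversity(0, c(0, 0)), "undefined")
  expect_true(is.na(f0))

  # identical composition of clusters: within-pi equals total pi
  set.seed(53)
  half <- matrix(sample(0:2, 4 * 15, TRUE), 4, 15)
  gm_same <- geno_matrix(rbind(half, half))
  cl <- rep(1:2, each = 4)
  expect_lt(fst(gm_same, cl), 0.35)  # same composition, modest structure

  # fixed opposite alleles: FST = 1
  gm_fix <- geno_matrix(rbind(matrix(0, 3, 10), matrix(2, 3, 10)))
  expect_equal(fst(gm_fix, rep(1:2, each = 3)), 1)

  # toy two-cluster configuration vs direct enumeration
  calls <- rbind(c(0, 2), c(0, 0), c(2, 2), c(2, 0))
  gm <- geno_matrix(calls)
  cl2 <- c(1, 1, 2, 2)
  D <- pairwise_divergence(gm)
  pi_t <- mean(D[lower.tri(D)])
  pi_1 <- D[1, 2]; pi_2 <- D[3, 4]
  expect_equal(fst(gm, cl2),
               (pi_t - weighted.mean(c(pi_1, pi_2), c(2, 2))) / pi_t)
})

test_that("diversity partitioning is coherent for structured populations", {
  # genuinely differentiated clusters: total diversity exceeds the weighted
  # within-cluster mean, so F_ST is positive before clamping
  set.seed(54)
  for (rep in 1:5) {
    p1 <- runif(40, 0.05, 0.45)
    p2 <- pmin(p1 + runif(40, 0.3, 0.5), 0.95)  # shifted frequencies
    c1 <- sapply(p1, function(p) rbinom(6, 2, p))
    c2 <- sapply(p2, function(p) rbinom(6, 2, p))
    gm <- geno_matrix(rbind(c1, c2))
    cl <- rep(1:2, each = 6)
    pi_t <- nucleotide_diversity(gm)
    groups <- split(sample_ids(gm), cl)
    pi_w <- vapply(groups, function(g) nucleotide_diversity(gm, g),
                   numeric(1))
    expect_gt(pi_t - weighted.mean(pi_w, c(6, 6)), 0)
  }
  # arbitrary partitions of homogeneous data can put the raw difference
  # slightly below zero by sampling noise; the clamp guarantees F_ST >= 0
  for (rep in 1:5) {
    calls <- matrix(sample(0:2, 12 * 25, TRUE), 12, 25)
    gm <- geno_matrix(calls)
    cl <- rep(1:3, each = 4)
    f <- fst(gm, sample(cl))
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("sibling exclusion selects one individual per family", {
  cfg <- sim_config(n_markers = 5, seed = 55)
  ped <- make_pedigree(cfg)
  sel <- select_unrelated(ped, n = 50, generation = 1, seed = 2)
  expect_length(sel, 50)
  g1 <- ped[ped$generation == 1, ]
  fams <- paste(g1$sire, g1$dam)[match(as.numeric(sel), g1$id)]
  expect_equal(anyDuplicated(fams), 0L)
  expect_identical(select_unrelated(ped, 50, 1, seed = 2), sel)
  expect_length(select_unrelated(ped, 1, 1, seed = 3), 1)
  expect_error(select_unrelated(ped, 58, 1), "57 families")
})

test_that("weight categories follow the left-closed bins", {
  w <- c(45, 71, 40, 29, 35, 55, 65)
  expect_equal(as.character(weight_categories(w)),
               c("II", "V", "II", "unbinned", "I", "III", "IV"))
})

test_that("tree cutting yields the requested number of clusters", {
  cfg <- sim_config(families_gen1 = 12, offspring_gen1 = c(2, 3),
                    families_gen2 = 0, n_markers = 300,
                    traits = list(flat_trait()), seed = 56)
  dat <- simulate_dataset(cfg)
  sel <- select_unrelated(dat$pedigree, 12, 1, seed = 1)
  gm <- geno_matrix(dat$genotypes$calls[sel, , drop = FALSE])
  tree <- neighbor_joining(pairwise_divergence(gm))
  cl <- cut_tree_clusters(tree, 4)
  expect_length(cl, 12)
  expect_equal(length(unique(cl)), 4)
  expect_setequal(names(cl), sel)
})
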