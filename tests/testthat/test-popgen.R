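toy_map <- function(m, chrom = 1, spacing = 1000) {
  data.frame(marker = paste0("m", seq_len(m)), chrom = chrom,
             pos_bp = seq_len(m) * spacing)
}

test_that("r2 is 1 for duplicated markers and invariant to allele flips", {
  set.seed(10)
  x <- rbinom(80, 2, 0.4)
  z <- rbinom(80, 2, 0.6)
  d <- cbind(m1 = x, m2 = x, m3 = z)
  g <- genotype_matrix(d, toy_map(3))
  pr <- ld_pairs(g)
  expect_equal(pr$r2[pr$marker_i == "m1" & pr$marker_j == "m2"], 1)

  # flipping the counted allele of one marker leaves r2 unchanged
  d2 <- cbind(m1 = x, m2 = 2 - x, m3 = z)
  pr2 <- ld_pairs(genotype_matrix(d2, toy_map(3)))
  expect_equal(pr$r2, pr2$r2, tolerance = 1e-12)
  # symmetry in marker order is implicit: each unordered pair appears once
  expect_equal(nrow(pr), 3)
})

test_that("gametic D is zero for independent loci in a phased toy", {
  # four individuals built from haplotypes AB/AB, Ab/Ab, aB/aB, ab/ab:
  # p(AB) = 0.25 = p(A) p(B), no double heterozygotes
  d <- cbind(m1 = c(2, 2, 0, 0), m2 = c(2, 0, 2, 0))
  g <- genotype_matrix(d, toy_map(2))
  pr <- ld_pairs(g, with_D = TRUE, min_maf = 0)
  expect_equal(pr$D, 0, tolerance = 1e-9)
})

test_that("independent markers show near-null mean r2 at large n", {
  set.seed(77)
  n <- 1000
  d <- sapply(runif(80, 0.2, 0.8), function(p) rbinom(n, 2, p))
  colnames(d) <- paste0("m", 1:80)
  g <- genotype_matrix(d, toy_map(80))
  pr <- ld_pairs(g, min_maf = 0)
  # E[r2] under independence is about 1/n
  expect_lt(mean(pr$r2), 3 / n)
  expect_gt(mean(pr$r2), 0.2 / n)
})

test_that("decay curve bins conserve the pair multiset", {
  pop <- small_pop()
  pr <- ld_pairs(pop$genotypes, max_distance_bp = 2e7)
  c1 <- ld_decay_curve(pr, 5e6)
  c2 <- ld_decay_curve(pr, 2.5e6)
  expect_equal(sum(c1$n_pairs), nrow(pr))
  expect_equal(sum(c2$n_pairs), nrow(pr))

  # all pairs at one distance: single occupied bin holding the grand mean
  d <- cbind(m1 = rbinom(50, 2, 0.5), m2 = rbinom(50, 2, 0.5),
             m3 = rbinom(50, 2, 0.5))
  map <- data.frame(marker = c("m1", "m2", "m3"), chrom = c(1, 1, 2),
                    pos_bp = c(0, 1000, 500))
  prs <- ld_pairs(genotype_matrix(d, map), min_maf = 0)
  expect_equal(nrow(prs), 1)  # same-chromosome pairs only
  cv <- ld_decay_curve(prs, 2000)
  expect_equal(cv$mean_r2[cv$n_pairs > 0], mean(prs$r2))
})

test_that("marker selection ranks by expected heterozygosity with id ties", {
  d <- cbind(lo = rbinom(60, 2, 0.5), hi = rbinom(60, 2, 0.5))
  # engineer exact frequencies: p = 0.05 vs p = 0.5
  d[, "lo"] <- c(rep(1, 6), rep(0, 54))
  d[, "hi"] <- c(rep(2, 15), rep(0, 15), rep(1, 30))
  g <- genotype_matrix(d)
  top <- select_informative_markers(g, 1)
  expect_equal(top$marker_ids, "hi")

  # equal frequencies everywhere: tie broken by marker id
  deq <- cbind(b = c(0, 2, 1, 1), a = c(1, 1, 2, 0), c = c(2, 0, 1, 1))
  geq <- genotype_matrix(deq)
  sel <- select_informative_markers(geq, 2)
  expect_equal(sel$marker_ids, c("a", "b"))

  # n = all markers returns the full set
  expect_setequal(select_informative_markers(g, 2)$marker_ids, c("lo", "hi"))
  expect_error(select_informative_markers(g, 3),
               class = "selfpred_validation_error")
})

test_that("LOD excludes impossible fathers at zero error rate", {
  # candidate C carries an allele nobody else has; offspring is heterozygous
  d <- rbind(MOM = c(0, 2, 1), C = c(2, 1, 1), X1 = c(0, 1, 1),
             X2 = c(0, 0, 2), KID = c(1, 2, 1))
  g <- genotype_matrix(d, toy_map(3))
  lod_c <- paternity_lod(g, "KID", "MOM", "C", error_rate = 0)
  lod_x1 <- paternity_lod(g, "KID", "MOM", "X1", error_rate = 0)
  lod_x2 <- paternity_lod(g, "KID", "MOM", "X2", error_rate = 0)
  expect_gt(lod_c, 0)
  expect_equal(lod_x1, -Inf)
  expect_equal(lod_x2, -Inf)
  expect_error(paternity_lod(g, "KID", "MOM", "nope"),
               class = "selfpred_lookup_error")
})

test_that("identical candidates receive identical LODs and Delta = 0", {
  set.seed(33)
  base <- rbinom(40, 2, 0.5)
  d <- rbind(MOM = rbinom(40, 2, 0.5), TW1 = base, TW2 = base,
             OTH = rbinom(40, 2, 0.5))
  kid <- rbinom(40, 1, d["MOM", ] / 2) + rbinom(40, 1, base / 2)
  d <- rbind(d, KID = kid)
  g <- genotype_matrix(d, toy_map(40))
  res <- assign_paternity(g, "KID", c(KID = "MOM"),
                          c("MOM", "TW1", "TW2", "OTH"), error_rate = 0.05)
  expect_equal(paternity_lod(g, "KID", "MOM", "TW1"),
               paternity_lod(g, "KID", "MOM", "TW2"))
  if (res$best_candidate %in% c("TW1", "TW2"))
    expect_equal(res$delta, 0, tolerance = 1e-12)
})

test_that("delta thresholds are reproducible and handle degenerate pools", {
  pop <- fixture_pop(n_parents = 12, offspring_per_parent = c(2, 3),
                     n_markers = 200, n_chromosomes = 2, missing_rate = 0,
                     seed = 61)
  sub <- select_informative_markers(impute_mean(pop$founders), 150)
  t1 <- delta_threshold(sub, n_replicates = 800, seed = 4)
  t2 <- delta_threshold(sub, n_replicates = 800, seed = 4)
  expect_identical(t1$delta_critical, t2$delta_critical)
  expect_gte(t1$delta_critical, 0)

  expect_warning(td <- delta_threshold(sub, candidate_ids = sub$individual_ids[1],
                                       n_replicates = 100),
                 "degenerate")
  expect_equal(td$delta_critical, 0)

  # perfect-information limit: distinct homozygous candidates, no error
  dperf <- rbind(A = rep(0, 30), B = rep(2, 30),
                 C = rep(c(0, 2), 15), D = rep(c(2, 0), 15))
  gperf <- genotype_matrix(dperf, toy_map(30))
  tp <- delta_threshold(gperf, error_rate = 0, n_replicates = 500, seed = 9)
  expect_equal(tp$delta_critical, 0)
  expect_equal(tp$success_rate, 1)
})

test_that("classify_offspring conserves counts for per-offspring input", {
  pop <- fixture_pop(n_parents = 10, offspring_per_parent = c(6, 9),
                     n_markers = 300, n_chromosomes = 3, missing_rate = 0,
                     genotyping_error_rate = 0.05, seed = 71)
  gi <- impute_mean(pop$genotypes)
  sub <- select_informative_markers(gi, 200)
  off <- pop$pedigree[!is.na(pop$pedigree$dam), ]
  cand <- unique(c(off$dam, off$sire))
  res <- assign_paternity(sub, off$id, setNames(off$dam, off$id), cand,
                          delta_relaxed = 0.5)
  summ <- classify_offspring(res)
  pf <- summ$per_family
  expect_equal(sum(pf$n_selfed + pf$n_crossed + pf$n_unassigned),
               nrow(off))
  expect_equal(summ$overall$total, nrow(off))

  # all offspring assigned to their mother -> 100% selfed
  allself <- res
  allself$assignment <- "selfed"
  s2 <- classify_offspring(allself)
  expect_equal(s2$overall$pct_selfed, 100)
})

test_that("the bundled family-count table reproduces the published totals", {
  fam <- utils::read.csv(system.file("extdata", "selfing_family_counts.csv",
                                     package = "selfpred"))
  summ <- classify_offspring(fam)
  expect_equal(summ$overall$total, 523)
  expect_equal(summ$overall$n_selfed, 326)
  expect_equal(summ$overall$n_crossed, 197)
  expect_equal(summ$overall$pct_selfed, 62.33)
  expect_equal(summ$overall$pct_crossed, 37.67)
  # GEN25: 32 seeds, all selfed
  g25 <- summ$per_family[summ$per_family$family == "GEN25", ]
  expect_equal(g25$pct_selfed, 100)
})
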