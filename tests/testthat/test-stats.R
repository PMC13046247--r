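test_that("chromosome density arithmetic and exclusion handling are exact", {
  layout <- make_genome_layout(1e6, "chr1")
  r <- data.frame(chrom = "chr1", pos = seq(0, 999000, by = 1000),
                  strand = "+", status = "target_unique")
  d <- density_by_chromosome(r, layout, total_mapped = 1e6)
  # 1000 reads on 1 Mb, library 1e6 -> 1.0 RPM/kb
  expect_equal(d$density, 1.0)
  # all reads inside the exclusion -> density 0 and shorter usable length
  lay2 <- make_genome_layout(1e6, "chr1",
                             exclusions = data.frame(chrom = "chr1",
                                                     start = 0, end = 5e5))
  r2 <- data.frame(chrom = "chr1", pos = c(10, 20, 499999), strand = "+",
                   status = "target_unique")
  d2 <- density_by_chromosome(r2, lay2, total_mapped = 1e6)
  expect_equal(d2$reads, 0)
  expect_equal(d2$usable_length, 5e5)
  expect_equal(d2$density, 0)
  expect_error(density_by_chromosome(r, layout, total_mapped = 0),
               "positive")
})

test_that("hotspot counts constant per chromosome give density decreasing
           with chromosome size", {
  lengths <- seq(2e5, 1e6, length.out = 8)
  layout <- make_genome_layout(lengths)
  fs <- plant_features(layout, n_hotspots = rep(4, 8), min_gap = 2000,
                       seed = 51)
  model <- occupancy_model(enrichment = c(hotspot = 30),
                           spike_fraction = 0, ambiguous_rate = 0)
  rd <- simulate_experiment(layout, fs, model, 2e5,
                            samples = two_sample_sheet(), seed = 52)
  d <- density_by_chromosome(rd$chip, layout)
  expect_equal(d$chrom[which.max(d$density)], layout$chrom_names[1])
  pc <- pearson_correlation(d$usable_length, d$density)
  expect_lt(pc$r, 0)
  expect_lt(pc$p, 0.05)
})

test_that("Pearson correlation is exact on constructed data", {
  x <- c(1, 2, 3, 4, 5)
  y <- -x
  pc <- pearson_correlation(x, y)
  expect_equal(pc$r, -1)
  # hand-computed 5-point dataset
  x2 <- c(1, 2, 3, 4, 5)
  y2 <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x2 - mean(x2)) * (y2 - mean(y2))) /
    sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  expect_equal(pearson_correlation(x2, y2)$r, r_hand)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               "undefined correlation")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("exact rank-sum p-values match the closed-form oracle", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3)
  expect_identical(w$method, "exact")
  # all tie-free shapes up to n = 10 against the pwilcox oracle
  set.seed(61)
  for (na in 2:5) for (nb in 2:5) {
    x <- sample(1000, na + nb)
    a <- x[seq_len(na)]
    b <- x[-seq_len(na)]
    mine <- wilcoxon_rank_sum(a, b, mode = "exact")
    u <- mine$W
    p_oracle <- min(1, 2 * min(pwilcox(u, na, nb),
                               1 - pwilcox(u - 1, na, nb)))
    expect_equal(mine$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("identical samples give p near 1 and the approximation tracks
           the exact path", {
  a <- c(1, 2, 3, 4, 5)
  expect_gt(wilcoxon_rank_sum(a, a)$p, 0.9)
  set.seed(62)
  for (rep in 1:10) {
    x <- sample(1e6, 24)
    a <- x[1:12]; b <- x[13:24]
    pe <- {
      u <- wilcoxon_rank_sum(a, b, mode = "normal")$W
      min(1, 2 * min(pwilcox(u, 12, 12), 1 - pwilcox(u - 1, 12, 12)))
    }
    pn <- wilcoxon_rank_sum(a, b, mode = "normal")$p
    expect_lt(abs(pn - pe), 0.01)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("rank-sum type-I error is calibrated at the 5% level", {
  set.seed(63)
  rej <- mean(replicate(500, {
    wilcoxon_rank_sum(rnorm(30), rnorm(30))$p < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("hotspot binding classes partition the hotspot set", {
  fs <- feature_set(rep("c1", 4), c(0, 1000, 2000, 3000),
                    c(500, 1500, 2500, 3500), "hotspot",
                    strength = c(10, 20, 30, 40))
  mkpk <- function(start, end) meiocal:::new_peak_set(
    data.frame(chrom = "c1", start = start, end = end, summit = 0,
               p_value = 0, q_value = 0, label = NA))
  pkA <- mkpk(c(0, 1000), c(400, 1400))
  pkB <- mkpk(c(1000, 2000), c(1600, 2600))
  cb <- classify_hotspot_binding(fs, pkA, pkB)
  expect_equal(cb$classes$class, c("A_only", "both", "B_only", "neither"))
  expect_equal(sum(table(cb$classes$class)), 4)
  expect_true(cb$comparison$defined)
  expect_equal(cb$comparison$median_A_only, 10)
  expect_equal(cb$comparison$median_B_only, 30)
  # degenerate: no A-specific hotspots -> comparison undefined, reported
  cb2 <- classify_hotspot_binding(fs, pkB[0, ], pkB)
  expect_false(cb2$comparison$defined)
})

test_that("SNP density per peak and genome tiles follow the definitions", {
  layout <- make_genome_layout(1e5, "c1")
  snps <- structure(list(c1 = c(100L, 300L, 600L, 900L, 50000L)),
                    layout = layout, class = "SNPMap")
  pk <- meiocal:::new_peak_set(data.frame(
    chrom = "c1", start = 0, end = 1000, summit = 500, p_value = 0,
    q_value = 0, label = NA))
  res <- snp_density_analysis(snps, pk, layout)
  expect_equal(res$per_peak$density, 4.0)  # 4 SNPs in a 1-kb peak
  expect_equal(length(res$tile_densities), 100)
  expect_equal(mean(res$tile_densities), 5 / 100)
  expect_error(snp_density_analysis(snps, transform(pk, end = start),
                                    layout), "zero-width|start")
})

test_that("uniform SNPs with random peaks are reported non-significant,
           planted deserts as depleted", {
  layout <- make_genome_layout(2e6, "c1")
  sm <- plant_snps(layout, 4, seed = 71)
  set.seed(72)
  starts <- sample.int(2e6 - 1000, 150)
  pk <- meiocal:::new_peak_set(data.frame(
    chrom = "c1", start = starts, end = starts + 1000, summit = 0,
    p_value = 0, q_value = 0, label = NA))
  res <- snp_density_analysis(sm, pk, layout)
  se <- sd(res$tile_densities) / sqrt(nrow(pk))
  expect_lt(abs(mean(res$per_peak$density) - res$genome_mean), 3 * se)
  # peaks placed in SNP deserts: significant depletion
  ok <- sapply(seq(0, 2e6 - 2000, by = 2000), function(s)
    sum(sm$c1 >= s & sm$c1 < s + 1000) == 0)
  desert <- seq(0, 2e6 - 2000, by = 2000)[ok][1:min(60, sum(ok))]
  pk2 <- meiocal:::new_peak_set(data.frame(
    chrom = "c1", start = desert, end = desert + 1000, summit = 0,
    p_value = 0, q_value = 0, label = NA))
  res2 <- snp_density_analysis(sm, pk2, layout)
  expect_lt(res2$test$p, 0.01)
  expect_lt(mean(res2$per_peak$density), res2$genome_mean)
})

test_that("crossover co-occupancy fractions are an exact partition and
           match brute force on a toy set", {
  co <- structure(data.frame(tetrad_id = 1:10, chrom = "c1",
                             pos = seq(5000, 95000, by = 10000)),
                  n_tetrads = 10L,
                  class = c("CrossoverSet", "data.frame"))
  mkpk <- function(start, end) meiocal:::new_peak_set(
    data.frame(chrom = "c1", start = start, end = end, summit = 0,
               p_value = 0, q_value = 0, label = NA))
  pkA <- mkpk(c(4000, 14000, 24000), c(6000, 16000, 26000))
  pkB <- mkpk(c(24000, 34000), c(26000, 36000))
  res <- crossover_cooccupancy(co, pkA, pkB, site_window = 2000)
  expect_equal(sum(res$fractions), 1)
  sites <- data.frame(chrom = co$chrom, start = co$pos - 1000,
                      end = co$pos + 1000)
  inA <- brute_overlaps_any(sites, pkA)
  inB <- brute_overlaps_any(sites, pkB)
  expect_equal(unname(res$counts),
               c(sum(inA & inB), sum(inA & !inB), sum(!inA & inB),
                 sum(!inA & !inB)))
  # all crossovers inside an A-and-B peak -> both = 100%
  res2 <- crossover_cooccupancy(co, mkpk(0, 1e5), mkpk(0, 1e5))
  expect_equal(unname(res2$fractions["both"]), 1)
  # no peaks -> neither = 100%
  res3 <- crossover_cooccupancy(co, pkA[0, ], pkB[0, ])
  expect_equal(unname(res3$fractions["neither"]), 1)
  expect_error(crossover_cooccupancy(co[0, ], pkA, pkB), "empty")
})

test_that("qPCR fold enrichment obeys its normalization identities", {
  loci <- c("cold", "hotA", "axisB")
  base <- expand.grid(locus = loci, strain = c("tagged", "untagged"),
                      stringsAsFactors = FALSE)
  base$ip_quantity <- 2
  base$input_quantity <- 4
  fe <- qpcr_enrichment(base, "cold")
  expect_equal(fe$fold_enrichment, rep(1, 3))
  # doubling one tagged locus ratio doubles its FE
  m2 <- base
  m2$ip_quantity[m2$locus == "hotA" & m2$strain == "tagged"] <- 4
  fe2 <- qpcr_enrichment(m2, "cold")
  expect_equal(fe2$fold_enrichment[fe2$locus == "hotA"], 2)
  expect_equal(fe2$fold_enrichment[fe2$locus == "cold"], 1)
  # permutation invariance
  fe3 <- qpcr_enrichment(m2[sample(nrow(m2)), ], "cold")
  expect_equal(fe3$fold_enrichment[match(fe2$locus, fe3$locus)],
               fe2$fold_enrichment)
  expect_error(qpcr_enrichment(base, "missing"), "coldspot")
  bad <- base; bad$ip_quantity[1] <- 0
  expect_error(qpcr_enrichment(bad, "cold"), "positive")
})

test_that("centromere distances and group comparison behave as planted", {
  layout <- make_genome_layout(rep(1e6, 4))
  cen <- data.frame(chrom = layout$chrom_names, start = 499900,
                    end = 500100, class = "centromere",
                    strength = NA_real_, name = NA_character_)
  near <- data.frame(chrom = layout$chrom_names, start = 519900,
                     end = 520400, class = "hotspot", strength = 5,
                     name = NA_character_)
  far <- data.frame(chrom = layout$chrom_names, start = 899900,
                    end = 900400, class = "hotspot", strength = 5,
                    name = NA_character_)
  fs <- meiocal:::validate_feature_set(rbind(cen, near, far), layout)
  rest <- fs[fs$class != "centromere", ]
  groups <- ifelse(rest$start < 6e5, "near", "far")
  res <- centromere_distance(fs, groups)
  expect_equal(sort(unique(res$distances$distance)), c(20150, 400150))
  expect_true(res$comparison$defined)
  expect_lt(res$comparison$p, 0.05)
  # feature centered exactly on the centromere -> distance 0
  fs0 <- meiocal:::validate_feature_set(rbind(cen, transform(
    near, start = 499900, end = 500100)), layout)
  res0 <- centromere_distance(fs0, rep(NA_character_, 4))
  expect_true(all(res0$distances$distance == 0))
  expect_false(res0$comparison$defined)
  expect_error(centromere_distance(fs[fs$class != "centromere", ],
                                   groups), "centromere")
})
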