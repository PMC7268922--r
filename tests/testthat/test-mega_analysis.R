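eff2 <- function(y, se, gene = "g") {
  data.frame(gene = gene, study_id = sprintf("s%d", seq_along(y)),
             y = y, se = se, stringsAsFactors = FALSE)
}

test_that("a single study is returned unchanged with trivial heterogeneity", {
  r <- fixed_effect(eff2(0.7, 0.2))
  expect_equal(r$pooled_lfc, 0.7)
  expect_equal(r$se_pooled, 0.2)
  expect_equal(r$Q, 0)
  expect_equal(r$df, 0L)
  expect_equal(r$isq, 0)
  expect_equal(r$p_q, 1)
  expect_equal(unname(r$weights), 1)
})

test_that("fixed-effect pooling matches closed forms", {
  r <- fixed_effect(eff2(c(1, 1), c(1, 1)))
  expect_equal(r$pooled_lfc, 1)
  expect_equal(r$se_pooled, sqrt(0.5))
  expect_equal(r$Q, 0)
  expect_equal(r$isq, 0)

  r2 <- fixed_effect(eff2(c(0, 2), c(1, 1)))
  expect_equal(r2$pooled_lfc, 1)
  expect_equal(r2$Q, 2)
  expect_equal(r2$df, 1L)
  expect_equal(r2$isq, 50)
  expect_equal(r2$p_q, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(sum(r2$weights), 1, tolerance = 1e-10)
  expect_equal(r2$ci_low, 1 - qnorm(0.975) * sqrt(0.5))
  expect_equal(r2$ci_high, 1 + qnorm(0.975) * sqrt(0.5))
  expect_error(fixed_effect(data.frame(y = numeric(), se = numeric())),
               "empty")
})

test_that("DerSimonian-Laird pooling matches the hand computation", {
  # Q = 2, C = 2 - 2/2 = 1, tau2 = 1, w* = (1/2, 1/2)
  r <- random_effect(eff2(c(0, 2), c(1, 1)))
  expect_equal(r$tau2, 1)
  expect_equal(unname(r$weights), c(0.5, 0.5))
  expect_equal(r$pooled_lfc, 1)
  expect_equal(r$se_pooled, 1)
  # heterogeneity block still reported from fixed-effect weights
  expect_equal(r$Q, 2)
  expect_equal(r$isq, 50)
  # Q <= df truncates tau2 to 0 and collapses onto the fixed model
  r0 <- random_effect(eff2(c(1, 1), c(1, 1)))
  f0 <- fixed_effect(eff2(c(1, 1), c(1, 1)))
  expect_equal(r0$tau2, 0)
  expect_equal(r0$pooled_lfc, f0$pooled_lfc)
  expect_equal(r0$se_pooled, f0$se_pooled)
  expect_error(random_effect(eff2(1, 1)), "at least 2")
})

test_that("DL tau2 matches the general 2-study closed form", {
  cases <- list(c(0.2, 1.4, 0.3, 0.6), c(-1, 1, 0.5, 0.5),
                c(0.1, 0.15, 0.2, 0.9))
  for (cs in cases) {
    y <- cs[1:2]; se <- cs[3:4]
    w <- 1 / se^2
    pooled <- sum(w * y) / sum(w)
    Q <- sum(w * (y - pooled)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - 1) / C)
    expect_equal(random_effect(eff2(y, se))$tau2, tau2)
  }
})

test_that("DL recovers a planted between-study variance on average", {
  set.seed(17)
  tau2s <- replicate(200, {
    y <- rnorm(50, 0, sqrt(0.25 + 0.01))
    random_effect(eff2(y, rep(0.1, 50)))$tau2
  })
  expect_true(mean(tau2s) > 0.15 && mean(tau2s) < 0.35)
})

test_that("pooled estimates agree with independent oracles", {
  set.seed(23)
  for (i in 1:50) {
    eff <- random_effects(sample(2:12, 1))
    o <- oracle_fixed(eff$y, eff$se)
    r <- fixed_effect(eff)
    expect_equal(r$pooled_lfc, o$pooled, tolerance = 1e-12)
    expect_equal(r$se_pooled, o$se, tolerance = 1e-12)
    expect_equal(r$Q, o$Q, tolerance = 1e-10)
  }
})

test_that("fixed and DL results agree with metafor on random instances", {
  skip_if_not_installed("metafor")
  set.seed(29)
  for (i in 1:10) {
    eff <- random_effects(sample(3:10, 1))
    fe <- fixed_effect(eff)
    mf <- metafor::rma(yi = eff$y, sei = eff$se, method = "FE")
    expect_equal(fe$pooled_lfc, as.numeric(mf$beta), tolerance = 1e-10)
    expect_equal(fe$se_pooled, mf$se, tolerance = 1e-10)
    expect_equal(fe$Q, mf$QE, tolerance = 1e-8)
    re <- random_effect(eff)
    md <- metafor::rma(yi = eff$y, sei = eff$se, method = "DL")
    expect_equal(re$tau2, md$tau2, tolerance = 1e-8)
    expect_equal(re$pooled_lfc, as.numeric(md$beta), tolerance = 1e-10)
    expect_equal(re$se_pooled, md$se, tolerance = 1e-10)
  }
})

test_that("auto mode selects the model from the truncated heterogeneity", {
  hom <- eff2(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_equal(mega(hom, "auto")$model, "fixed")
  het <- eff2(c(0, 2), c(1, 1))
  m <- mega(het, "auto")
  expect_equal(m$model, "random")
  expect_equal(m$isq, 50)
  # explicit modes override the rule
  expect_equal(mega(het, "fixed")$model, "fixed")
  expect_equal(mega(hom, "random")$model, "random")
  # the fixed <=> isq = 0 equivalence in auto mode on random instances
  set.seed(31)
  for (i in 1:30) {
    eff <- random_effects(sample(2:9, 1))
    r <- mega(eff, "auto")
    expect_equal(r$model == "fixed", r$isq == 0)
  }
})

test_that("mega results are invariant to study order", {
  set.seed(37)
  eff <- random_effects(9)
  perm <- eff[sample(9), ]
  a <- mega(eff, "auto"); b <- mega(perm, "auto")
  for (f in c("pooled_lfc", "se_pooled", "p", "Q", "isq", "p_q", "tau2"))
    expect_equal(a[[f]], b[[f]])
  expect_equal(a$weights[sort(names(a$weights))],
               b$weights[sort(names(b$weights))])
  pa <- partial_select(eff); pb <- partial_select(perm)
  expect_setequal(pa$study_id, pb$study_id)
})

test_that("adding a study at the pooled value never widens the pooled se", {
  set.seed(41)
  for (i in 1:20) {
    eff <- random_effects(sample(2:8, 1))
    r <- fixed_effect(eff)
    extra <- data.frame(gene = "g", study_id = "new", y = r$pooled_lfc,
                        se = runif(1, 0.05, 2))
    r2 <- fixed_effect(rbind(eff, extra))
    expect_lte(r2$se_pooled, r$se_pooled)
    expect_equal(r2$pooled_lfc, r$pooled_lfc, tolerance = 1e-12)
  }
})

test_that("random and fixed estimates coincide in the homogeneous limit", {
  eff <- eff2(rep(0.4, 6), rep(0.3, 6))
  expect_equal(random_effect(eff)$pooled_lfc,
               fixed_effect(eff)$pooled_lfc, tolerance = 1e-10)
  expect_equal(random_effect(eff)$se_pooled,
               fixed_effect(eff)$se_pooled, tolerance = 1e-10)
})

test_that("partial selection keeps floor(k/2) records by |effect|", {
  expect_equal(nrow(partial_select(random_effects(9))), 4L)
  expect_equal(nrow(partial_select(random_effects(8))), 4L)
  expect_equal(nrow(partial_select(random_effects(1))), 1L)
  sel <- partial_select(eff2(c(0.1, -0.5, 0.2), c(0.3, 0.3, 0.3)))
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$y, -0.5)
  # ties on |y| break by smaller se, then study_id
  tie <- eff2(c(0.5, -0.5, 0.5), c(0.3, 0.2, 0.3))
  expect_equal(partial_select(tie)$study_id, "s2")
  tie2 <- eff2(c(0.5, 0.5), c(0.3, 0.3))
  expect_equal(partial_select(tie2)$study_id, "s1")
})

test_that("partial mega-analysis reduces to the full one when possible", {
  same <- eff2(rep(0.8, 6), rep(0.2, 6))
  expect_equal(partial_mega(same, "auto")$pooled_lfc,
               mega(same, "auto")$pooled_lfc)
  one <- eff2(0.3, 0.2)
  p1 <- partial_mega(one, "auto")
  expect_equal(p1$pooled_lfc, mega(one, "auto")$pooled_lfc)
  expect_equal(p1$analysis, "partial")
})

test_that("partial analysis amplifies a signal carried by a study subset", {
  # 4 of 9 studies carry the effect; the top-50% rule must pick them up
  eff <- eff2(c(rep(1.2, 4), rep(0.05, 5)), rep(0.2, 9))
  full <- mega(eff, "fixed")
  part <- partial_mega(eff, "fixed")
  expect_equal(sort(partial_select(eff)$study_id), sprintf("s%d", 1:4))
  expect_gt(abs(part$pooled_lfc), abs(full$pooled_lfc))
})

test_that("the significance filter applies strict asymmetric thresholds", {
  expect_true(significance_filter(0.51, p = 1.53e-9))
  expect_false(significance_filter(-0.49, p = 2.19e-2))
  expect_true(significance_filter(-0.89, p = 2.12e-8))
  # boundaries are strict
  expect_false(significance_filter(0.49, p = 1e-12))
  expect_false(significance_filter(-0.74, p = 1e-12))
  expect_false(significance_filter(0.51, p = 1e-7))
  # works on mega_result objects too
  r <- fixed_effect(eff2(rep(0.6, 9), rep(0.05, 9)))
  expect_true(significance_filter(r))
  expect_error(significance_filter(0.5), "supply p-values")
})

test_that("mega_table reports paired full/partial rows with a gene flag", {
  eff <- rbind(eff2(c(rep(1.2, 4), rep(0.02, 5)), rep(0.08, 9), "GPART"),
               eff2(rep(0.02, 9), rep(0.08, 9), "GNULL"))
  tab <- mega_table(eff, mode = "auto")
  expect_equal(nrow(tab), 4L)
  expect_equal(sort(unique(tab$analysis)), c("MA", "partial-MA"))
  gp <- tab[tab$gene == "GPART", ]
  expect_true(gp$significant[gp$analysis == "partial-MA"])
  expect_true(all(gp$gene_significant))
  gn <- tab[tab$gene == "GNULL", ]
  expect_false(any(gn$significant))
  expect_false(any(gn$gene_significant))
  expect_equal(gp$k[gp$analysis == "partial-MA"], 4L)
})

test_that("forest tables carry per-study CIs and normalized weights", {
  eff <- eff2(c(0.2, 0.8, 0.5), c(0.1, 0.2, 0.4))
  r <- mega(eff, "fixed")
  ft <- forest_table(r)
  expect_equal(ft$study_id, eff$study_id)
  expect_equal(ft$ci_low, eff$y - qnorm(0.975) * eff$se)
  expect_equal(ft$ci_high, eff$y + qnorm(0.975) * eff$se)
  expect_equal(sum(ft$weight), 1, tolerance = 1e-10)
  expect_true(all(ft$weight > 0 & ft$weight < 1))
})
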