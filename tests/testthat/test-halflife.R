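tp7 <- c(5, 10, 20, 30, 60, 120, 240)

test_that("noiseless exponentials are fit exactly", {
    x <- rbind(g1 = 100 * 2^(-tp7 / 120),
               g2 = 50 * 2^(-tp7 / 30))
    de <- DecayExperiment(x, tp7, replicate = rep(1, 7))
    rec <- fitDecay(de)
    expect_equal(rec$k_per_min[1], log(2) / 120, tolerance = 1e-9)
    expect_equal(rec$tau_min[1], 120, tolerance = 1e-9)
    expect_equal(rec$tau_min[2], 30, tolerance = 1e-9)
    expect_equal(rec$tau_min * rec$k_per_min, rep(log(2), 2))
    expect_true(all(rec$qc_pass))
})

test_that("degenerate series are handled without false positives", {
    x <- rbind(const = rep(80, 7), zero = rep(0, 7))
    de <- DecayExperiment(x, tp7, replicate = rep(1, 7))
    rec <- fitDecay(de)
    expect_false(rec$qc_pass[1])   # no decay: k ~ 0, cv explodes
    expect_true(abs(rec$k_per_min[1]) < 1e-6)
    expect_false(rec$qc_pass[2])   # all-zero series cannot be fit
    expect_true(is.na(rec$k_per_min[2]))
    short <- DecayExperiment(rbind(g = c(9, 5, 3)), c(5, 10, 20),
                             replicate = rep(1, 3))
    expect_error(fitDecay(short), "4 distinct timepoints")
})

test_that("fitted decay rates agree with an independent grid search", {
    sim <- simulateDecayExperiment(nGenes = 40, noiseCV = 0.1, seed = 13)
    rec <- fitDecay(sim$experiment)
    x <- assay(sim$experiment, "rpkm")
    tp <- colData(sim$experiment)$timepoint_min
    tsh <- tp - min(tp)
    for (g in sample(rownames(x), 10)) {
        R0 <- mean(x[g, tp == min(tp)])
        k_oracle <- gridSearchK(as.numeric(x[g, ]), tsh, R0)
        k_fit <- rec$k_per_min[rec$gene_id == g]
        expect_lt(abs(k_fit - k_oracle), 1e-6)
    }
})

test_that("reference rescaling anchors the reference gene exactly", {
    # reference already decaying at the anchor half-life: factors are 1
    x <- rbind(MA1574 = 100 * 2^(-tp7 / 120), g2 = 70 * 2^(-tp7 / 45))
    de <- DecayExperiment(x, tp7, replicate = rep(1, 7))
    sc <- referenceScale(de, "MA1574", 120)
    expect_equal(assay(sc, "rpkm"), x, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(metadata(sc)$reference_correction$factor, rep(1, 7))
    # with drift and noise: fitted reference half-life is exactly 120
    sim <- simulateDecayExperiment(nGenes = 30, noiseCV = 0.15,
                                   driftAmplitude = 0.2, seed = 21)
    sc2 <- referenceScale(sim$experiment, "MA1574", 120)
    rec <- fitDecay(sc2)
    expect_equal(rec$tau_min[rec$gene_id == "MA1574"], 120,
                 tolerance = 1e-6)
    # idempotence
    sc3 <- referenceScale(sc2, "MA1574", 120)
    expect_equal(assay(sc3, "rpkm"), assay(sc2, "rpkm"), tolerance = 1e-12)
    expect_error(referenceScale(de, "absent"), "not present")
})

test_that("rescaling removes a planted global drift", {
    sim <- simulateDecayExperiment(nGenes = 120, noiseCV = 0.05,
                                   driftAmplitude = 0.3, seed = 8)
    raw <- fitDecay(sim$experiment)
    cor_rec <- fitDecay(referenceScale(sim$experiment, "MA1574", 120))
    truth <- sim$truth$true_halflife_min
    err <- function(rec) {
        ok <- rec$qc_pass
        median(abs(rec$tau_min[ok] - truth[ok]) / truth[ok])
    }
    expect_lt(err(cor_rec), 0.15)      # truth recovered after correction
    expect_lt(err(cor_rec), err(raw))  # correction strictly helps
})

test_that("QC filtering is exactly the stated predicate", {
    set.seed(3)
    rec <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      k_per_min = rnorm(200, 0.01, 0.02),
                      se_k = abs(rnorm(200, 0.002, 0.002)))
    rec$tau_min <- log(2) / rec$k_per_min
    rec$cv <- rec$se_k / rec$k_per_min
    kept <- qcFilter(rec)
    brute <- rec[rec$k_per_min > 0 & rec$cv < 0.5, ]
    expect_identical(kept$gene_id, brute$gene_id)
    expect_true(all(kept$gene_id %in% rec$gene_id))
    # closed cases
    one <- data.frame(gene_id = "a", k_per_min = 0.01, se_k = 0.003,
                      tau_min = 69.3, cv = 0.3)
    expect_equal(nrow(qcFilter(one)), 1)
    one$k_per_min <- -0.01; one$cv <- -0.3
    expect_equal(nrow(qcFilter(one)), 0)
})

test_that("cell-cycle scaling reproduces hand arithmetic", {
    rec <- data.frame(gene_id = "g", k_per_min = log(2) / 159,
                      tau_min = 159, se_k = 1e-5, cv = 0.01)
    sb <- scaleByDoubling(rec, 24.6)
    expect_equal(sb$fractions$fraction, 159 / (24.6 * 60), tolerance = 1e-12)
    rec$tau_min <- 24.6 * 60; rec$k_per_min <- log(2) / (24.6 * 60)
    expect_equal(scaleByDoubling(rec, 24.6)$fractions$fraction, 1)
    expect_error(scaleByDoubling(rec, 0), "positive")
})

test_that("constant cell-cycle fraction is invariant across doubling times", {
    frac <- 0.127
    tds <- c(7.5, 8.9, 24.6)
    sims <- lapply(seq_along(tds), function(i)
        simulateDecayExperiment(
            nGenes = 80, noiseCV = 0.08, seed = 30 + i,
            halflifeDist = list(dist = "lognormal",
                                meanlog = log(frac * tds[i] * 60),
                                sdlog = 0.25)))
    fracs <- lapply(seq_along(tds), function(i) {
        rec <- qcFilter(fitDecay(sims[[i]]$experiment))
        scaleByDoubling(rec, tds[i])$fractions$fraction
    })
    expect_gt(t.test(fracs[[1]], fracs[[3]])$p.value, 0.01)
    expect_gt(t.test(fracs[[2]], fracs[[3]])$p.value, 0.01)
})

test_that("half-life shift calls follow the propagated t-test", {
    rec <- data.frame(gene_id = c("a", "b"),
                      k_per_min = log(2) / c(60, 100),
                      tau_min = c(60, 100),
                      se_k = c(1e-4, 1e-4), cv = c(0.05, 0.05),
                      df_resid = c(19, 19))
    rec$cv <- rec$se_k / rec$k_per_min
    same <- classifyShift(rec, rec)
    expect_true(all(same$class == "no_change"))
    expect_true(all(same$pvalue == 1))
    # tau 60 +- 1 vs 160 +- 2 (SE): >30 sigma separation
    a <- data.frame(gene_id = "g", k_per_min = log(2) / 60, tau_min = 60,
                    se_k = log(2) * 1 / 60^2,    # se_tau = 1 min
                    cv = NA, df_resid = 19)
    a$cv <- a$se_k / a$k_per_min
    b <- a; b$tau_min <- 160; b$k_per_min <- log(2) / 160
    b$se_k <- log(2) * 2 / 160^2                 # se_tau = 2 min
    b$cv <- b$se_k / b$k_per_min
    call <- classifyShift(a, b)
    expect_identical(call$class, "longer")
    expect_lt(call$pvalue, 1e-6)
})

test_that("shift-call false-positive rate is near alpha under the null", {
    # simulated replicate fits under identical true half-lives
    set.seed(99)
    n <- 4000
    tau <- 90
    se_tau <- 6
    df <- 19
    make <- function() {
        tau_hat <- tau + se_tau * stats::rnorm(n)
        k <- log(2) / tau_hat
        data.frame(gene_id = sprintf("g%04d", 1:n), k_per_min = k,
                   tau_min = tau_hat,
                   se_k = se_tau * k^2 / log(2), cv = NA, df_resid = df)
    }
    a <- make(); b <- make()
    a$cv <- a$se_k / a$k_per_min; b$cv <- b$se_k / b$k_per_min
    calls <- classifyShift(a, b, alpha = 0.01)
    fpr <- mean(calls$class != "no_change")
    expect_lt(fpr, 1.5 * 0.01)
    expect_gt(fpr, 0.01 / 3)
})

test_that("rank-sum comparison matches exact enumeration for small n", {
    set.seed(5)
    x <- c(12.1, 15.3, 9.8, 20.2, 11.0)
    y <- c(14.2, 18.9, 25.1, 16.4)
    res <- compareDistributions(x, y)
    expect_equal(res$pvalue, exactRankSumP(x, y), tolerance = 1e-12)
    # identical distributions
    same <- compareDistributions(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 0.5))
    expect_gt(same$pvalue, 0.5)
    # complete separation
    far <- compareDistributions(rnorm(50, 0), rnorm(50, 100))
    expect_lt(far$pvalue, 1e-10)
    expect_error(compareDistributions(numeric(), y), "empty")
})

test_that("category summaries equal a brute-force group-by", {
    set.seed(6)
    rec <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      k_per_min = runif(60, 0.003, 0.02),
                      se_k = runif(60, 1e-4, 1e-3))
    rec$tau_min <- log(2) / rec$k_per_min
    rec$cv <- rec$se_k / rec$k_per_min
    ann <- setNames(sample(LETTERS[1:5], 60, replace = TRUE), rec$gene_id)
    ann <- ann[1:50]    # leave some genes unannotated
    sm <- summarizeByCategory(rec, ann)
    expect_true("unclassified" %in% sm$category)
    for (cc in setdiff(sm$category, "unclassified")) {
        genes <- names(ann)[ann == cc]
        sub <- rec[rec$gene_id %in% genes, ]
        expect_equal(sm$median_tau[sm$category == cc], median(sub$tau_min))
        se_tau <- log(2) * sub$se_k / sub$k_per_min^2
        w <- 1 / se_tau^2
        mu <- mean(sub$tau_min)
        expect_equal(sm$weighted_sd[sm$category == cc],
                     sqrt(sum(w * (sub$tau_min - mu)^2) / sum(w)))
    }
    # simple medians
    tri <- data.frame(gene_id = c("a", "b", "c"),
                      k_per_min = log(2) / c(60, 120, 240),
                      tau_min = c(60, 120, 240), se_k = 1e-5, cv = 1e-3)
    expect_equal(summarizeByCategory(tri, setNames(rep("Z", 3),
                                                   tri$gene_id))$median_tau,
                 120)
})
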