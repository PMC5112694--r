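test_that("steady-state transcription rate and copy numbers behave", {
    expect_equal(transcriptionRate(0, 0.01), 0)
    expect_equal(transcriptionRate(10, log(2) / 120), 10 * log(2) / 120)
    # algebraic inverse on random pairs
    set.seed(1)
    m <- runif(50, 0.1, 100); g <- runif(50, 1e-3, 0.1)
    expect_equal(transcriptionRate(m, g) / g, m)
    expect_error(transcriptionRate(1, 0), "positive")
    # dilution flag
    expect_equal(transcriptionRate(10, 0.01, mu = 0.002), 10 * 0.012)
    # copies per cell
    expect_equal(copiesPerCell(c(a = 5), 1000), c(a = 1000))
    rp <- c(a = 1, b = 99)
    expect_equal(copiesPerCell(rp, 1000)[["a"]], 10)
    set.seed(2)
    x <- setNames(runif(30), paste0("g", 1:30))
    cp <- copiesPerCell(x, 750)
    expect_equal(sum(cp), 750)
    expect_error(copiesPerCell(c(a = 0), 10), "zero")
})

test_that("control coefficients satisfy their closed forms and identity", {
    # abundance doubles, gamma unchanged: purely transcriptional
    cc <- controlCoefficients(1, 2, 0.01, 0.01)
    expect_equal(cc$rho_D, 0)
    expect_equal(cc$rho_T, 1)
    # k_trn unchanged (gamma halves as m doubles): purely degradational
    cc <- controlCoefficients(1, 2, 0.01, 0.005)
    expect_equal(cc$rho_D, 1)
    expect_equal(cc$rho_T, 0, tolerance = 1e-12)
    # m x4, gamma x1/2 -> rho_D = ln2/ln4 = 0.5
    cc <- controlCoefficients(1, 4, 0.02, 0.01)
    expect_equal(cc$rho_D, 0.5)
    expect_equal(cc$rho_T, 0.5)
    # identity to 1e-12 over 10,000 random determinate inputs
    set.seed(7)
    n <- 10000
    m1 <- runif(n, 0.01, 1000); m2 <- m1 * exp(runif(n, 0.1, 3) *
                                               sample(c(-1, 1), n, TRUE))
    g1 <- runif(n, 1e-4, 0.5); g2 <- runif(n, 1e-4, 0.5)
    cc <- controlCoefficients(m1, m2, g1, g2)
    expect_true(all(cc$determinate))
    expect_lt(max(abs(cc$rho_T + cc$rho_D - 1)), 1e-12)
    # equal abundances: indeterminate sentinel, not an explosion
    cc <- controlCoefficients(5, 5, 0.01, 0.02)
    expect_true(is.na(cc$rho_D))
    expect_false(cc$determinate)
    expect_error(controlCoefficients(-1, 2, 0.1, 0.1), "positive")
})

test_that("control coefficients are invariant to the expression scale", {
    set.seed(8)
    m1 <- runif(100, 1, 100); m2 <- runif(100, 1, 100)
    g1 <- runif(100, 1e-3, 0.1); g2 <- runif(100, 1e-3, 0.1)
    a <- controlCoefficients(m1, m2, g1, g2)
    b <- controlCoefficients(m1 * 3.7, m2 * 3.7, g1, g2)
    expect_equal(a$rho_D, b$rho_D, tolerance = 1e-9)
    expect_identical(classifyRegime(a$rho_D), classifyRegime(b$rho_D))
})

test_that("regime thresholds are applied exactly as defined", {
    expect_identical(
        classifyRegime(c(-0.3, 0, 0.5, 1, 1.2, NA)),
        c("transcriptional", "transcriptional", "shared", "degradational",
          "degradational", "indeterminate"))
})

test_that("planted pure regimes are classified perfectly without noise", {
    set.seed(9)
    n <- 500
    m1 <- runif(n, 1, 100)
    fold <- exp(runif(n, 0.5, 2) * sample(c(-1, 1), n, TRUE))
    m2 <- m1 * fold
    g1 <- runif(n, 1e-3, 0.1)
    # transcriptionally driven: gamma fixed
    cc_t <- controlCoefficients(m1, m2, g1, g1)
    expect_true(all(classifyRegime(cc_t$rho_D) == "transcriptional"))
    # degradationally driven: k_trn fixed, gamma = k/m
    g2 <- g1 * m1 / m2
    cc_d <- controlCoefficients(m1, m2, g1, g2)
    expect_true(all(classifyRegime(cc_d$rho_D) == "degradational"))
})

test_that("control analysis marks QC failures indeterminate", {
    rec <- function(k, cv) data.frame(
        gene_id = c("a", "b"), k_per_min = k, tau_min = log(2) / k,
        se_k = cv * k, cv = cv, df_resid = 19)
    a <- rec(c(0.01, 0.02), c(0.1, 0.7))   # gene b fails QC
    b <- rec(c(0.02, 0.02), c(0.1, 0.1))
    ctl <- controlAnalysis(a, b, c(a = 10, b = 10), c(a = 40, b = 40))
    expect_identical(ctl$regime[ctl$gene_id == "b"], "indeterminate")
    expect_false(is.na(ctl$rho_D[ctl$gene_id == "a"]))
    expect_equal(ctl$rho_T + ctl$rho_D, c(1, NA_real_))
})

test_that("consensus DEG set is the intersection of thresholded sets", {
    tab <- function(p) data.frame(gene_id = sprintf("g%03d", seq_along(p)),
                                  pvalue = p)
    t1 <- tab(c(0.005, 0.005, 0.5))
    t2 <- tab(c(0.009, 0.020, 0.002))
    t3 <- tab(c(0.002, 0.002, 0.009))
    res <- consensusDEG(list(edgeR = t1, DESeq2 = t2, PoissonSeq = t3))
    expect_identical(res$gene_id[res$consensus], "g001")
    # g002 fails: one method above alpha
    expect_false(res$consensus[res$gene_id == "g002"])
    # random tables vs brute force; consensus is a subset of every method set
    set.seed(10)
    tabs <- lapply(1:3, function(i) tab(runif(300)))
    names(tabs) <- paste0("m", 1:3)
    res <- consensusDEG(tabs, alpha = 0.3)
    brute <- Reduce(intersect, lapply(tabs, function(tt)
        tt$gene_id[tt$pvalue <= 0.3]))
    expect_setequal(res$gene_id[res$consensus], brute)
    for (s in attr(res, "method_sets"))
        expect_true(all(res$gene_id[res$consensus] %in% s))
    # mismatched universes rejected in strict mode
    t4 <- tab(runif(5))
    expect_error(consensusDEG(list(a = tabs[[1]], b = t4)), "universe")
    expect_error(consensusDEG(tabs, alpha = 1.5), "alpha")
    expect_error(consensusDEG(tabs[1]), "two method tables")
})

test_that("the built-in DE test is calibrated and powered", {
    # identical replicate vectors: p = 1
    cts <- matrix(c(10, 20, 10, 20, 10, 20), 2, 3,
                  dimnames = list(c("a", "b"), NULL))
    de <- simpleDETest(cts, cts)
    expect_true(all(de$pvalue == 1))
    expect_error(simpleDETest(cts[, 1, drop = FALSE], cts), "2 replicates")
    # planted 16-fold change, low dispersion
    sim <- simulateCountExperiment(nGenes = 100,
                                   plantedLog2FC = c(gene0001 = 4),
                                   dispersion = 0.01, nReplicates = 3,
                                   seed = 12)
    cond <- colData(sim$counts)$condition
    cts <- assay(sim$counts, "counts")
    de <- simpleDETest(cts[, cond == "cond1"], cts[, cond == "cond2"])
    expect_lte(de$pvalue[de$gene_id == "gene0001"], 0.01)
    # null calibration
    null_sim <- simulateCountExperiment(nGenes = 5000, dispersion = 0.1,
                                        nReplicates = 5, seed = 14)
    cond <- colData(null_sim$counts)$condition
    cts <- assay(null_sim$counts, "counts")
    de <- simpleDETest(cts[, cond == "cond1"], cts[, cond == "cond2"])
    fpr <- mean(de$pvalue <= 0.05)
    expect_gt(fpr, 0.02)
    expect_lt(fpr, 0.08)
})

test_that("bootstrap DEG uncertainty shrinks with replicates", {
    # zero-noise data: identical replicates give zero resampling variance
    base <- matrix(rep(c(10, 100, 1000), 3), 3, 3,
                   dimnames = list(c("a", "b", "c"), NULL))
    alt <- base * 4
    bs <- bootstrapDEGUncertainty(base, alt, B = 50, seed = 4)
    expect_equal(bs$relativeSD, 0)
    # determinism
    sim <- simulateCountExperiment(
        nGenes = 300,
        plantedLog2FC = setNames(rep(2, 30), sprintf("gene%04d", 1:30)),
        nReplicates = 10, seed = 15)
    cond <- colData(sim$counts)$condition
    cts <- assay(sim$counts, "counts")
    a3 <- cts[, which(cond == "cond1")[1:3]]
    b3 <- cts[, which(cond == "cond2")[1:3]]
    r1 <- bootstrapDEGUncertainty(a3, b3, B = 100, seed = 5)
    r2 <- bootstrapDEGUncertainty(a3, b3, B = 100, seed = 5)
    expect_identical(r1$counts, r2$counts)
    # variance shrinkage: 10 replicates vs 3
    r10 <- bootstrapDEGUncertainty(cts[, cond == "cond1"],
                                   cts[, cond == "cond2"],
                                   B = 100, seed = 5)
    expect_lt(r10$relativeSD, r1$relativeSD)
    expect_error(bootstrapDEGUncertainty(a3, b3, B = 1), "B must be")
})
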