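test_that("noiseless decay datasets are exact exponentials", {
    sim <- simulateDecayExperiment(nGenes = 10, noiseCV = 0,
                                   driftAmplitude = 0, seed = 42)
    x <- assay(sim$experiment, "rpkm")
    tp <- colData(sim$experiment)$timepoint_min
    for (g in sample(rownames(x), 4)) {
        tau <- sim$truth$true_halflife_min[sim$truth$gene_id == g]
        R0 <- sim$truth$true_initial[sim$truth$gene_id == g]
        expect_equal(unname(x[g, ]), R0 * 2^(-tp / tau), tolerance = 1e-12)
    }
    # designated reference gene present with half-life 120
    expect_true("MA1574" %in% sim$truth$gene_id)
    expect_equal(
        sim$truth$true_halflife_min[sim$truth$gene_id == "MA1574"], 120)
    expect_equal(sum(sim$truth$gene_id == "MA1574"), 1)
})

test_that("generators are deterministic under a fixed seed", {
    a <- simulateDecayExperiment(nGenes = 30, noiseCV = 0.2,
                                 driftAmplitude = 0.1, seed = 7)
    b <- simulateDecayExperiment(nGenes = 30, noiseCV = 0.2,
                                 driftAmplitude = 0.1, seed = 7)
    expect_identical(assay(a$experiment, "rpkm"),
                     assay(b$experiment, "rpkm"))
    expect_identical(a$truth, b$truth)
    ca <- simulateCountExperiment(nGenes = 50, seed = 11)
    cb <- simulateCountExperiment(nGenes = 50, seed = 11)
    expect_identical(assay(ca$counts, "counts"),
                     assay(cb$counts, "counts"))
    ta <- makeToyModel(plantedShift = c(P1 = 0.5), seed = 3)
    tb <- makeToyModel(plantedShift = c(P1 = 0.5), seed = 3)
    expect_identical(ta$ref@expression, tb$ref@expression)
})

test_that("invalid generator settings are rejected", {
    expect_error(simulateDecayExperiment(timepoints = c(10, 5, 20)),
                 "increasing")
    expect_error(simulateDecayExperiment(noiseCV = -0.1), "noiseCV")
    expect_error(
        simulateCountExperiment(nGenes = 10,
                                plantedLog2FC = c(nosuch = 2)),
        "unknown gene")
    expect_error(simulateCountExperiment(dispersion = 0), "dispersion")
    expect_error(makeToyModel(plantedShift = c(X99 = 2)),
                 "absent from biomass")
})

test_that("count generator plants the requested fold changes", {
    # null case: no planted DEG, condition means agree in expectation
    null_sim <- simulateCountExperiment(nGenes = 2000, dispersion = 0.05,
                                        nReplicates = 10, seed = 5)
    cts <- assay(null_sim$counts, "counts")
    cond <- colData(null_sim$counts)$condition
    ratio <- rowMeans(cts[, cond == "cond2"]) /
        pmax(rowMeans(cts[, cond == "cond1"]), 1)
    expect_lt(abs(median(log2(ratio))), 0.1)
    # planted log2fc = 2 recovered as ~4-fold mean ratio at large n
    sim <- simulateCountExperiment(
        nGenes = 200, plantedLog2FC = c(gene0001 = 2),
        dispersion = 0.05, nReplicates = 400, seed = 6)
    cts <- assay(sim$counts, "counts")
    cond <- colData(sim$counts)$condition
    r1 <- mean(cts["gene0001", cond == "cond2"]) /
        mean(cts["gene0001", cond == "cond1"])
    expect_equal(r1, 4, tolerance = 0.1)
})

test_that("planted DEGs are recoverable by the built-in test", {
    planted <- setNames(rep(c(2, -2), 25), sprintf("gene%04d", 1:50))
    sim <- simulateCountExperiment(nGenes = 1000, plantedLog2FC = planted,
                                   dispersion = 0.1, nReplicates = 3,
                                   seed = 9)
    cts <- assay(sim$counts, "counts")
    cond <- colData(sim$counts)$condition
    de <- simpleDETest(cts[, cond == "cond1"], cts[, cond == "cond2"])
    hits <- de$gene_id[de$pvalue <= 0.01]
    recovery <- mean(names(planted) %in% hits)
    expect_gte(recovery, 0.8)
    # high-replicate oracle: same planted effects, n = 50 -> full recovery
    sim50 <- simulateCountExperiment(nGenes = 1000, plantedLog2FC = planted,
                                     dispersion = 0.1, nReplicates = 50,
                                     seed = 9)
    cts50 <- assay(sim50$counts, "counts")
    cond50 <- colData(sim50$counts)$condition
    de50 <- simpleDETest(cts50[, cond50 == "cond1"],
                         cts50[, cond50 == "cond2"])
    expect_gte(mean(names(planted) %in%
                    de50$gene_id[de50$pvalue <= 0.01]), 0.99)
})

test_that("toy model is consistent, feasible and matches its ground truth", {
    toy <- makeToyModel(plantedShift = c(P3 = 2), seed = 2)
    S <- stoichMatrix(toy$model)
    # conversion reactions balance: columns other than exchange/biomass
    conv <- setdiff(reactionIds(toy$model),
                    c(exchangeReactions(toy$model),
                      biomassReaction(toy$model)))
    expect_true(all(abs(colSums(S[, conv])) < 1e-12))
    expect_true(length(reactionIds(toy$model)) >= 15 &&
                length(reactionIds(toy$model)) <= 25)
    # feasible with positive growth at default bounds
    sol <- fbaSolve(toy$model)
    expect_identical(solverStatus(sol), "optimal")
    expect_gt(objectiveValue(sol), 0)
    # flux ratios at matched growth equal the emitted expression ratios
    mu1 <- growthRate(toy$ref); mu2 <- growthRate(toy$alt)
    v1 <- fluxes(matchGrowth(toy$model, "EX_substrate", mu1)$solution)
    shifted <- setBiomassCoefficient(toy$model, "P3",
                                     2 * biomassCoefficients(toy$model)["P3"])
    v2 <- fluxes(matchGrowth(shifted, "EX_substrate", mu2)$solution)
    for (j in 1:6) {
        g <- paste0("gA", j)
        expect_equal(v1[paste0("BRA", j)] / v2[paste0("BRA", j)],
                     unname(toy$ref@expression[g] / toy$alt@expression[g]),
                     tolerance = 1e-5, ignore_attr = TRUE)
    }
})

test_that("null toy model has unit flux and expression ratios", {
    toy <- makeToyModel(refDoubling = 10, altDoubling = 10, seed = 4)
    expect_true(all(toy$truth$class == "unchanged"))
    expect_true(all(abs(toy$ref@expression - toy$alt@expression) < 1e-12))
    mu <- growthRate(toy$ref)
    v1 <- fluxes(matchGrowth(toy$model, "EX_substrate", mu)$solution)
    v2 <- fluxes(matchGrowth(toy$model, "EX_substrate", mu)$solution)
    expect_equal(v1, v2, tolerance = 1e-9)
})
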