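# Independent oracles and small fixture builders shared across the suite.

# Dense grid search + golden-section refinement for the decay rate that
# minimizes the pooled sum of squares of R0*exp(-k t).  Independent of the
# Levenberg-Marquardt path used by fitDecay.
gridSearchK <- function(y, t, R0, kmin = 1e-6, kmax = 1) {
    sse <- function(k) sum((y - R0 * exp(-k * t))^2)
    ks <- exp(seq(log(kmin), log(kmax), length.out = 2000))
    vals <- vapply(ks, sse, numeric(1))
    i <- which.min(vals)
    lo <- ks[max(1, i - 1)]; hi <- ks[min(length(ks), i + 1)]
    stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
}

# Enumerate the vertices of {v : S v = 0, lb <= v <= ub} by fixing n - rank
# variables at a bound and solving for the rest; returns the best objective.
vertexEnumBest <- function(S, lb, ub, obj) {
    S <- as.matrix(S)
    n <- ncol(S)
    r <- qr(S)$rank
    free <- n - r
    best <- -Inf
    for (fix_idx in combn(n, free, simplify = FALSE)) {
        rest <- setdiff(seq_len(n), fix_idx)
        Ssub <- S[, rest, drop = FALSE]
        if (qr(Ssub)$rank < r) next
        bounds <- expand.grid(rep(list(c(1, 2)), free))
        for (bi in seq_len(nrow(bounds))) {
            v <- numeric(n)
            v[fix_idx] <- ifelse(unlist(bounds[bi, ]) == 1,
                                 lb[fix_idx], ub[fix_idx])
            rhs <- -S[, fix_idx, drop = FALSE] %*% v[fix_idx]
            sol <- tryCatch(qr.solve(Ssub, rhs), error = function(e) NULL)
            if (is.null(sol)) next
            v[rest] <- sol
            if (max(abs(S %*% v)) > 1e-8) next
            if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
            best <- max(best, sum(obj * v))
        }
    }
    best
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments
# (small samples, no ties).
exactRankSumP <- function(x, y) {
    nx <- length(x); ny <- length(y)
    ranks <- rank(c(x, y))
    U_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
    idx <- combn(nx + ny, nx, simplify = FALSE)
    allranks <- rank(c(x, y))
    Us <- vapply(idx, function(i)
        sum(allranks[i]) - nx * (nx + 1) / 2, numeric(1))
    p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
    min(p, 1)
}

# Tiny linear chain model: EX_A (uptake) -> A --R1--> B --biomass-->
# with unit yield; biomass consumes B with coefficient 1.
chainModel <- function(uptake = 10) {
    metabolicModel(
        metabolites = data.frame(id = c("A", "B"), compartment = "c"),
        reactions = c("EX_A", "R1", "BIOMASS"),
        stoichiometry = list(c(A = -1), c(A = -1, B = 1), c(B = -1)),
        lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
        gpr = c("", "g1", ""),
        biomass = "BIOMASS", exchanges = "EX_A")
}

# CountMatrix fixture with known totals.
smallCounts <- function(counts = NULL) {
    if (is.null(counts))
        counts <- matrix(c(100, 200, 300, 400, 500, 600), nrow = 3,
                         dimnames = list(c("g1", "g2", "g3"),
                                         c("s1", "s2")))
    CountMatrix(counts,
                length = setNames(c(1000, 2000, 500), rownames(counts)),
                sampleData = data.frame(
                    condition = c("a", "b"), replicate = c(1, 1)))
}
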