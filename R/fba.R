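# Linear-programming layer: converts flux problems to the standard form
# min c'x, Ax = b, x >= 0 solved by the compiled simplex kernel.

# Default bound used to replace infinite flux bounds; fluxes in these models
# are O(1)-O(100) mmol/gDW/h so 1e4 is never active at an optimum.
.BIGBOUND <- 1e4

# Solve max/min obj'v subject to S v = 0, lb <= v <= ub.
# Returns list(status, v, objective).
.solveFluxLP <- function(S, lb, ub, obj, maximize = TRUE) {
    n <- ncol(S); m <- nrow(S)
    lb <- pmax(lb, -.BIGBOUND)
    ub <- pmin(ub, .BIGBOUND)
    if (any(lb > ub)) return(list(status = "infeasible"))
    # x = v - lb >= 0 ; rows: S x = -S lb ; x + s = ub - lb
    A <- rbind(cbind(S, matrix(0, m, n)), cbind(diag(n), diag(n)))
    b <- c(as.numeric(-S %*% lb), ub - lb)
    cc <- c(if (maximize) -obj else obj, rep(0, n))
    r <- .Call_simplex_core(A, b, cc)
    if (r$status != 0)
        return(list(status = c("infeasible", "unbounded",
                               "maxit")[r$status]))
    v <- as.numeric(r$x)[seq_len(n)] + lb
    list(status = "optimal", v = v, objective = sum(obj * v))
}

# Parsimonious refinement: minimize sum |v| at (near-)fixed objective value.
.solvePfbaLP <- function(S, lb, ub, obj, optValue, slack = 1e-9) {
    n <- ncol(S); m <- nrow(S)
    lb <- pmax(lb, -.BIGBOUND)
    ub <- pmin(ub, .BIGBOUND)
    # vars: x (= v - lb), t, s_ub, e_obj, e1, e2  -> 5n + 1 columns
    In <- diag(n)
    A <- rbind(
        cbind(S, matrix(0, m, 4 * n + 1)),
        c(obj, rep(0, n), rep(0, n), -1, rep(0, 2 * n)),
        cbind(In, matrix(0, n, n), In, matrix(0, n, 1),
              matrix(0, n, 2 * n)),
        cbind(-In, In, matrix(0, n, n), matrix(0, n, 1), -In,
              matrix(0, n, n)),
        cbind(In, In, matrix(0, n, n), matrix(0, n, 1),
              matrix(0, n, n), -In))
    b <- c(as.numeric(-S %*% lb),
           optValue - sum(obj * lb) - slack,
           ub - lb,
           lb,
           -lb)
    cc <- c(rep(0, n), rep(1, n), rep(0, 3 * n + 1))
    r <- .Call_simplex_core(A, b, cc)
    if (r$status != 0) return(NULL)
    as.numeric(r$x)[seq_len(n)] + lb
}

#' Flux balance analysis
#'
#' Solves the linear program \eqn{\max c'v} subject to steady-state mass
#' balance \eqn{S v = 0} and flux bounds \eqn{lb \le v \le ub}, where the
#' objective is a single reaction (by default the model's biomass reaction).
#' Because optimal flux vectors of an LP are generally not unique, the
#' returned vector can optionally be made deterministic by parsimonious
#' selection: among all optima, the one minimizing \eqn{\sum_r |v_r|} is
#' reported.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id to maximize (default the biomass reaction).
#' @param parsimonious logical; refine to the minimum total-flux optimum
#'   (default \code{TRUE}).
#' @return a \linkS4class{FluxSolution}; \code{solverStatus()} is
#'   \code{"infeasible"} or \code{"unbounded"} (with empty fluxes) when no
#'   optimum exists -- never silent zeros.
#' @examples
#' m <- makeToyModel()
#' sol <- fbaSolve(m$model)
#' objectiveValue(sol)   # growth rate at default uptake bound
#' @export
fbaSolve <- function(model, objective = biomassReaction(model),
                     parsimonious = TRUE) {
    stopifnot(is(model, "MetabolicModel"))
    j <- match(objective, model@reactions)
    if (is.na(j)) stop("unknown objective reaction: ", objective)
    S <- as.matrix(model@stoichiometry)
    obj <- numeric(ncol(S)); obj[j] <- 1
    r <- .solveFluxLP(S, model@lowerBounds, model@upperBounds, obj)
    if (r$status != "optimal")
        return(new("FluxSolution", fluxes = numeric(), objectiveValue = NA_real_,
                   objectiveId = objective, status = r$status))
    v <- r$v
    if (parsimonious) {
        vp <- .solvePfbaLP(S, model@lowerBounds, model@upperBounds, obj,
                           r$objective)
        if (!is.null(vp)) v <- vp
    }
    new("FluxSolution", fluxes = setNames(v, model@reactions),
        objectiveValue = r$objective, objectiveId = objective,
        status = "optimal")
}

#' Tune substrate uptake to match a measured growth rate
#'
#' Finds, by bisection, the substrate uptake bound at which the maximal
#' growth rate equals a measured value \code{targetMu} (1/h), typically
#' \code{log(2)/doubling_time}.  Exchange reactions are oriented
#' \code{met ->}, so uptake capacity \code{u} corresponds to a lower bound
#' of \code{-u} on the exchange flux.  Growth must be monotone
#' non-decreasing in the uptake bound (true for substrate-limited models).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param substrateExchange id of the substrate exchange reaction.
#' @param targetMu target growth rate (1/h), >= 0.
#' @param maxUptake largest uptake considered (default 1000 mmol/gDW/h).
#' @param tol convergence tolerance on |mu - targetMu| (default 1e-6).
#' @param parsimonious forwarded to [fbaSolve()] for the returned solution.
#' @return list with \code{uptake} (bound found), \code{solution} (a
#'   \linkS4class{FluxSolution} at that bound) and \code{model} (the model
#'   with the bound installed).
#' @export
matchGrowth <- function(model, substrateExchange, targetMu,
                        maxUptake = 1000, tol = 1e-6,
                        parsimonious = TRUE) {
    stopifnot(is(model, "MetabolicModel"))
    j <- match(substrateExchange, model@reactions)
    if (is.na(j)) stop("unknown exchange reaction: ", substrateExchange)
    if (!is.finite(targetMu) || targetMu < 0)
        stop("targetMu must be a non-negative growth rate")
    S <- as.matrix(model@stoichiometry)
    n <- ncol(S); m <- nrow(S)
    jb <- match(model@biomassId, model@reactions)
    lb <- pmax(model@lowerBounds, -.BIGBOUND)
    ub <- pmin(model@upperBounds, .BIGBOUND)
    # standard-form constraint matrix is bound-independent: build it once,
    # the bisection only updates the right-hand side
    A <- rbind(cbind(S, matrix(0, m, n)), cbind(diag(n), diag(n)))
    cc <- numeric(2 * n); cc[jb] <- -1
    muAt <- function(u) {
        lb2 <- lb; lb2[j] <- -u
        r <- .Call_simplex_core(A, c(as.numeric(-S %*% lb2), ub - lb2), cc)
        if (r$status != 0) NA_real_
        else as.numeric(r$x)[jb] + lb2[jb]
    }
    if (targetMu == 0) {
        u <- 0
    } else {
        hi_mu <- muAt(maxUptake)
        if (!is.finite(hi_mu) || hi_mu < targetMu - tol)
            stop("target growth rate ", targetMu,
                 " unreachable at maximum uptake ", maxUptake)
        # invariant: mu(lo) < target <= mu(hi); return hi, whose capped
        # solution reproduces the target exactly
        lo <- 0; hi <- maxUptake
        for (i in seq_len(200)) {
            if (muAt(hi) - targetMu < tol || hi - lo < 1e-12 * max(1, hi))
                break
            mid <- (lo + hi) / 2
            mu <- muAt(mid)
            if (!is.finite(mu) || mu < targetMu) lo <- mid else hi <- mid
        }
        u <- hi
    }
    model2 <- setFluxBounds(model, substrateExchange, lb = -u)
    # cap growth at the target so the reported solution reproduces mu
    model2 <- setFluxBounds(model2, model@biomassId,
                            ub = min(model@upperBounds[jb], targetMu))
    sol <- fbaSolve(model2, parsimonious = parsimonious)
    list(uptake = u, solution = sol, model = model2)
}

# Fast evaluator used by fitBiomassCoefficients: returns a closure that maps
# a biomass stoichiometry column to the growth-matched parsimonious flux
# vector (or NULL when the growth rate is unreachable).  Capping the biomass
# flux at the target growth rate and minimizing total flux is algebraically
# equivalent to tuning the uptake bound until the target growth is achieved
# and then solving parsimoniously: the minimum-total-flux solution takes up
# exactly the substrate the target growth requires.  Constraint matrices are
# prebuilt once; only the biomass column and right-hand sides change per
# candidate, which keeps the ~1e4 evaluations of a fitting run cheap.
.makeFluxEvaluator <- function(S, lb, ub, jBio, muTarget,
                               slack = 1e-9) {
    n <- ncol(S); m <- nrow(S)
    lb <- pmax(lb, -.BIGBOUND)
    ub <- pmin(ub, .BIGBOUND)
    ub[jBio] <- min(ub[jBio], muTarget)
    if (lb[jBio] != 0)
        stop("biomass reaction must have lower bound 0")
    In <- diag(n)
    A1 <- rbind(cbind(S, matrix(0, m, n)), cbind(In, In))
    cc1 <- numeric(2 * n); cc1[jBio] <- -1
    Sx0 <- S; Sx0[, jBio] <- 0
    b1_base <- as.numeric(-Sx0 %*% lb)   # lb[jBio] = 0: no biomass term
    Ap <- rbind(
        cbind(S, matrix(0, m, 4 * n + 1)),
        c(replace(numeric(n), jBio, 1), rep(0, n), rep(0, n), -1,
          rep(0, 2 * n)),
        cbind(In, matrix(0, n, n), In, matrix(0, n, 1),
              matrix(0, n, 2 * n)),
        cbind(-In, In, matrix(0, n, n), matrix(0, n, 1), -In,
              matrix(0, n, n)),
        cbind(In, In, matrix(0, n, n), matrix(0, n, 1),
              matrix(0, n, n), -In))
    ccp <- c(rep(0, n), rep(1, n), rep(0, 3 * n + 1))
    bp_tail <- c(ub - lb, lb, -lb)
    force(muTarget)
    function(bioCol) {
        A1[seq_len(m), jBio] <- bioCol
        Ap[seq_len(m), jBio] <- bioCol
        b1 <- c(b1_base, ub - lb)
        r1 <- .Call_simplex_core(A1, b1, cc1)
        if (r1$status != 0) return(NULL)
        mu <- as.numeric(r1$x)[jBio] + lb[jBio]
        if (mu < muTarget - 1e-7) return(NULL)
        bp <- c(b1_base, muTarget - slack, bp_tail)
        rp <- .Call_simplex_core(Ap, bp, ccp)
        if (rp$status != 0) return(NULL)
        as.numeric(rp$x)[seq_len(n)] + lb
    }
}
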