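test_that("read allocation obeys the class structure exactly", {
    classes <- list(1L, c(1L, 2L), c(2L, 3L))
    # singleton classes are deterministic
    set.seed(1)
    X <- allocateReads(classes, f = c(12L, 0L, 0L), pi = c(0.2, 0.5, 0.3))
    expect_identical(as.vector(X), c(12L, 0L, 0L))
    # degenerate proportions force all reads to the supported transcript
    X <- allocateReads(classes, f = c(0L, 50L, 0L), pi = c(1, 0, 0))
    expect_identical(as.vector(X), c(50L, 0L, 0L))
    # conservation: total allocated equals total class reads, always
    for (r in 1:50) {
        f <- sample(0:30, 3, replace = TRUE)
        p <- as.vector(latentDTU:::rdirichlet(1, c(1, 1, 1)))
        X <- allocateReads(classes, f, p)
        expect_equal(sum(X), sum(f))
        expect_gte(min(X), 0)
    }
})

test_that("symmetric two-transcript classes split reads binomially", {
    set.seed(2)
    draws <- replicate(5000, allocateReads(list(c(1L, 2L)), 1000L,
                                           c(0.5, 0.5))[1])
    # mean within 3 binomial standard errors of 500
    expect_lt(abs(mean(draws) - 500), 3 * sqrt(1000 * 0.25 / 5000))
    # variance in the binomial ballpark
    expect_lt(abs(var(draws) / 250 - 1), 0.15)
})

test_that("multi-gene classes weight transcripts by gene read mass", {
    # class shared between genes with equal within-gene proportions:
    # allocation follows the mass ratio
    set.seed(3)
    classes <- list(c(1L, 2L))
    draws <- replicate(3000, allocateReads(
        classes, 100L, pi = c(1, 1), geneOf = c(1L, 2L),
        geneMass = c(30, 10))[1])
    expect_lt(abs(mean(draws) / 100 - 0.75), 0.02)
})

test_that("all-zero allocation probabilities fall back to uniform", {
    set.seed(4)
    draws <- replicate(2000, allocateReads(list(c(1L, 2L)), 10L,
                                           pi = c(0, 0))[1])
    expect_lt(abs(mean(draws) - 5), 3 * sqrt(10 * 0.25 / 2000) * 5)
    expect_gt(var(draws), 0)
})

test_that("pi updates draw from the conjugate Dirichlet", {
    set.seed(5)
    # Dirichlet(delta + X) = Dirichlet(4, 2): mean 2/3
    draws <- replicate(1e5, gibbsUpdatePi(c(3, 1), c(1, 1))[1])
    se <- sd(draws) / sqrt(1e5)
    expect_lt(abs(mean(draws) - 2 / 3), 3 * se)
    # X = 0 is a draw from the prior Dirichlet(2,2): variance 1/20
    draws0 <- replicate(1e5, gibbsUpdatePi(c(0, 0), c(2, 2))[1])
    expect_lt(abs(mean(draws0) - 0.5), 3 * sd(draws0) / sqrt(1e5))
    expect_lt(abs(var(draws0) - 0.05), 0.002)
})

test_that("length correction matches the closed form and normalises", {
    expect_equal(computePiBarT(c(2, 2), c(100, 100)), c(0.5, 0.5))
    expect_equal(computePiBarT(c(2, 2), c(100, 300)), c(0.75, 0.25))
    set.seed(6)
    for (r in 1:20) {
        K <- sample(2:6, 1)
        d <- rgamma(K, 2)
        l <- runif(K, 100, 3000)
        expect_equal(sum(computePiBarT(d, l)), 1)
    }
    # matrix form: equal lengths reduce to the mapping proportions
    m <- matrix(rgamma(30, 2), ncol = 3)
    expect_equal(computePiBarT(m, rep(500, 3)), m / rowSums(m))
})

test_that("the sampler is deterministic given a seed", {
    cl <- makeCluster(list(1L, c(1L, 2L), 2L),
                      counts = c(20L, 15L, 8L, 18L, 12L, 9L))
    pr <- informativePrior()
    run <- function(s) suppressWarnings(
        runGeneMCMC(cl, pr, groups = factor(c("A", "B")),
                    niter = 500, burnin = 100, seed = s))
    a <- run(77)
    b <- run(77)
    expect_identical(a@delta, b@delta)
    expect_identical(a@logPosterior, b@logPosterior)
    c2 <- run(78)
    expect_false(identical(a@delta, c2@delta))
})

test_that("Metropolis acceptance stays in a healthy band on model data", {
    set.seed(8)
    # K = 2, N = 6, delta = (20, 10): simulate from the model itself
    p <- latentDTU:::rdirichlet(6, c(20, 10))
    x <- vapply(seq_len(6), function(i)
        as.vector(rmultinom(1, 400, p[i, ])), numeric(2))
    cl <- makeCluster(list(1L, 2L), counts = as.vector(t(x)))
    ch <- runGeneMCMC(cl, informativePrior(), groups = factor(rep("A", 6)),
                      niter = 4000, burnin = 1000, seed = 9)
    expect_gt(ch@acceptance[1, 1], 0.1)
    expect_lt(ch@acceptance[1, 1], 0.6)
})

test_that("MCMC matches the enumeration/quadrature oracle on a tiny cluster", {
    # K = 2, N = 1, classes {(T1): 3, (T1,T2): 5}: enumerate the 6
    # allocations of the ambiguous class, integrate pi analytically
    # (Beta functions) and delta by 2-D quadrature against the prior
    pr <- informativePrior(mean = log(30), var = 0.25)
    g <- seq(-25, 9, by = 0.04)
    l1 <- rep(g, times = length(g))
    l2 <- rep(g, each = length(g))
    d1 <- exp(l1); d2 <- exp(l2); dp <- d1 + d2
    pri <- dnorm(l1, pr@meanLogPrec - log(2), sqrt(pr@vagueVar),
                 log = TRUE) +
        dnorm(log(dp), pr@meanLogPrec, sqrt(pr@varLogPrec), log = TRUE) +
        l2 - log(dp)
    ll <- vapply(0:5, function(x)
        lchoose(5, x) + lgamma(dp) - lgamma(dp + 8) +
            lgamma(d1 + 3 + x) - lgamma(d1) +
            lgamma(d2 + 5 - x) - lgamma(d2) + pri,
        numeric(length(d1)))
    w <- exp(ll - max(ll))
    oracle <- sum(w * (d1 / dp)) / sum(w)

    cl <- makeCluster(list(1L, c(1L, 2L)), counts = c(3L, 5L))
    ch <- suppressWarnings(runGeneMCMC(cl, pr, groups = factor("A"),
                                       niter = 20000, burnin = 2000,
                                       seed = 4))
    dd <- exp(ch@delta$G1$A)
    pib <- dd[, 1] / rowSums(dd)
    expect_lt(abs(mean(pib) - oracle), 3 * mcse(pib))
})

test_that("unique-mapping data matches a direct Dirichlet-multinomial fit", {
    # all classes singletons: transcript counts observed; the posterior of
    # pi-bar under the DM marginal is computable by 2-D quadrature
    set.seed(10)
    x <- matrix(c(30L, 20L, 26L, 14L, 35L, 25L, 22L, 28L), nrow = 2)
    pr <- informativePrior(mean = log(20), var = 0.25)
    g <- seq(-20, 8, by = 0.04)
    l1 <- rep(g, times = length(g))
    l2 <- rep(g, each = length(g))
    d1 <- exp(l1); d2 <- exp(l2); dp <- d1 + d2
    pri <- dnorm(l1, pr@meanLogPrec - log(2), sqrt(pr@vagueVar),
                 log = TRUE) +
        dnorm(log(dp), pr@meanLogPrec, sqrt(pr@varLogPrec), log = TRUE) +
        l2 - log(dp)
    ll <- pri
    for (i in seq_len(ncol(x))) {
        n <- sum(x[, i])
        ll <- ll + lgamma(dp) - lgamma(n + dp) +
            lgamma(d1 + x[1, i]) - lgamma(d1) +
            lgamma(d2 + x[2, i]) - lgamma(d2)
    }
    w <- exp(ll - max(ll))
    oracle <- sum(w * (d1 / dp)) / sum(w)

    cl <- makeCluster(list(1L, 2L), counts = as.vector(rbind(x[1, ], x[2, ])))
    ch <- runGeneMCMC(cl, pr, groups = factor(rep("A", 4)),
                      niter = 20000, burnin = 2000, seed = 12)
    dd <- exp(ch@delta$G1$A)
    pib <- dd[, 1] / rowSums(dd)
    expect_lt(abs(mean(pib) - oracle), 3 * mcse(pib))
})

test_that("Geweke-style successive-conditional run reproduces the prior", {
    # alternate "data given parameters" (X ~ MN(n, pi)) and "parameters
    # given data" (pi ~ Dir(delta + X); Metropolis on log delta): the
    # invariant distribution of the joint chain is prior x model, so the
    # marginal of log delta_+ must match the prior
    pr <- informativePrior(mean = 2, var = 0.5)
    K <- 2; N <- 3; n <- 50
    set.seed(14)
    delta <- rPriorDelta(1, pr, K)[1, ]
    pi <- latentDTU:::rdirichlet(N, delta)
    target <- function(ld, piMat) {
        d <- exp(ld)
        sum(apply(piMat, 1, function(p)
            lgamma(sum(d)) - sum(lgamma(d)) +
                sum((d - 1) * log(pmax(p, 1e-12))))) +
            logPriorDensity(d, pr)
    }
    sweeps <- 20000
    keep <- numeric(sweeps)
    ld <- log(delta)
    for (s in seq_len(sweeps)) {
        X <- t(vapply(seq_len(N), function(i)
            as.vector(rmultinom(1, n, pi[i, ])), numeric(K)))
        pi <- t(vapply(seq_len(N), function(i)
            gibbsUpdatePi(X[i, ], exp(ld)), numeric(K)))
        prop <- ld + rnorm(K, 0, 0.4)
        if (log(runif(1)) < target(prop, pi) - target(ld, pi)) ld <- prop
        keep[s] <- log(sum(exp(ld)))
    }
    ref <- log(rowSums(rPriorDelta(20000, pr, K)))
    qs <- seq(0.1, 0.9, by = 0.1)
    expect_lt(max(abs(quantile(keep, qs) - quantile(ref, qs))), 0.12)
})

test_that("equal effective lengths make the expression scale identical", {
    cl <- makeCluster(list(1L, c(1L, 2L), 2L),
                      counts = c(25L, 10L, 30L), effLen = c(800, 800))
    ch <- suppressWarnings(runGeneMCMC(cl, informativePrior(),
                                       groups = factor("A"),
                                       niter = 1000, burnin = 200,
                                       seed = 3))
    dd <- exp(ch@delta$G1$A)
    piBar <- dd / rowSums(dd)
    piT <- computePiBarT(dd, ch@effLen$G1)
    expect_equal(piT, piBar)
})
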