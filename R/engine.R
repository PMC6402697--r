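## Internal mean-field variational EM engines.
##
## Data layout: a model input is a list over modalities; each modality is a
## list of one or more feature count matrices (D x V). Full-context catalogs
## have a single feature; independent-encoded catalogs have one matrix per
## mutation feature, all sharing the modality's signature block. Each
## modality m owns a block of K[m] coordinates of the shared logistic-normal
## variable eta_d; theta_d^(m) is the softmax of that block.
##
## The intractable E[log sum_k exp(eta_k)] term is handled with the standard
## first-order auxiliary-normalizer upper bound, one normalizer per sample
## and modality block; with the normalizer at its optimum the bound term
## collapses to N_dm * logsumexp_k(lambda_dk + nu2_dk / 2), which is what the
## compiled objective uses. Per-sample Gaussian parameters (lambda, log nu2)
## for all samples are updated jointly by L-BFGS-B; every update is a
## coordinate-ascent step, so the recorded ELBO trace is non-decreasing.

softmax_rows <- function(x) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
}

logsumexp_rows <- function(x) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
}

## catalogs (list of MutationCatalog) -> engine input
prep_input <- function(catalogs) {
    catalogs <- check_catalog_list(catalogs)
    Xs <- lapply(catalogs, function(cat) counts(cat, simplify = FALSE))
    for (m in seq_along(Xs)) {
        tot <- sum(vapply(Xs[[m]], sum, 0))
        if (tot <= 0) {
            stop("modality '", names(Xs)[m], "' has an all-zero count matrix")
        }
    }
    Xs
}

block_index <- function(K) {
    ends <- cumsum(K)
    starts <- ends - K + 1L
    lapply(seq_along(K), function(m) starts[m]:ends[m])
}

## per-modality token totals (D x M); independent features each emit a token
token_totals <- function(Xs) {
    D <- nrow(Xs[[1L]][[1L]])
    vapply(Xs, function(feats) {
        Reduce(`+`, lapply(feats, rowSums))
    }, numeric(D))
}

dirichlet_elbo <- function(gamma, beta) {
    V <- ncol(gamma)
    Elog <- digamma(gamma) - digamma(rowSums(gamma))
    prior <- lgamma(V * beta) - V * lgamma(beta) +
        rowSums((beta - 1) * Elog)
    entq <- lgamma(rowSums(gamma)) - rowSums(lgamma(gamma)) +
        rowSums((gamma - 1) * Elog)
    sum(prior) - sum(entq)
}

elog_dirichlet <- function(gamma) {
    digamma(gamma) - digamma(rowSums(gamma))
}

point_phi <- function(gamma) gamma / rowSums(gamma)

## average per-mutation log-likelihood of counts under point estimates,
## per modality (Eq-1 form, summed over features for independent catalogs)
point_trainll <- function(Xs, phis, thetas) {
    vapply(seq_along(Xs), function(m) {
        num <- 0
        den <- 0
        for (f in seq_along(Xs[[m]])) {
            P <- thetas[[m]] %*% phis[[m]][[f]]
            num <- num + sum(Xs[[m]][[f]] * log(P))
            den <- den + sum(Xs[[m]][[f]])
        }
        num / den
    }, 0)
}

## ---------------------------------------------------------------- MMCTM --

mmctm_init <- function(Xs, K, seed = NULL) {
    D <- nrow(Xs[[1L]][[1L]])
    Ktot <- sum(K)
    if (!is.null(seed)) set.seed(seed)
    list(
        gamma = lapply(seq_along(Xs), function(m) {
            lapply(Xs[[m]], function(X) {
                matrix(as.double(sample.int(100L, K[m] * ncol(X),
                    replace = TRUE)), K[m], ncol(X))
            })
        }),
        Lambda = matrix(0, D, Ktot),
        Nu2 = matrix(1, D, Ktot),
        mu = rep(0, Ktot),
        Sigma = diag(Ktot)
    )
}

mmctm_engine <- function(Xs, K, beta = 1, fixSigma = FALSE, tol = 1e-5,
        maxIter = 1000L, seed = NULL, init = NULL, ridge = 1e-6,
        innerMaxit = 100L) {
    M <- length(Xs)
    D <- nrow(Xs[[1L]][[1L]])
    Ktot <- sum(K)
    blocks <- block_index(K)
    bstart <- vapply(blocks, function(b) b[1L] - 1L, 1L)
    bsize <- K
    Nmat <- token_totals(Xs)
    st <- if (is.null(init)) mmctm_init(Xs, K, seed) else init
    gamma <- st$gamma
    Lambda <- st$Lambda
    Nu2 <- st$Nu2
    mu <- st$mu
    Sigma <- st$Sigma
    lower <- c(rep(-30, D * Ktot), rep(-20, D * Ktot))
    upper <- c(rep(30, D * Ktot), rep(5, D * Ktot))
    elbo <- numeric(0)
    ll_prev <- NULL
    ll <- NULL
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        U <- chol(Sigma)
        SigInv <- chol2inv(U)
        logdet <- 2 * sum(log(diag(U)))
        Elogphi <- lapply(gamma, function(g) lapply(g, elog_dirichlet))
        s <- matrix(0, D, Ktot)
        gstat <- vector("list", M)
        xlogz <- 0
        for (m in seq_len(M)) {
            gstat[[m]] <- vector("list", length(Xs[[m]]))
            for (f in seq_along(Xs[[m]])) {
                r <- resp_stats(Xs[[m]][[f]], Elogphi[[m]][[f]],
                    Lambda[, blocks[[m]], drop = FALSE])
                s[, blocks[[m]]] <- s[, blocks[[m]]] + r$s
                gstat[[m]][[f]] <- r$gstat
                xlogz <- xlogz + r$xlogz
            }
        }
        ## ELBO at the current state (responsibilities fresh)
        A <- sweep(Lambda, 2L, mu)
        gauss <- -0.5 * D * logdet -
            0.5 * sum((A %*% SigInv) * A) -
            0.5 * sum(sweep(Nu2, 2L, diag(SigInv), `*`)) -
            0.5 * D * Ktot * log(2 * pi)
        ent_eta <- 0.5 * sum(log(2 * pi * Nu2) + 1)
        bound <- 0
        for (m in seq_len(M)) {
            lse <- logsumexp_rows(Lambda[, blocks[[m]], drop = FALSE] +
                0.5 * Nu2[, blocks[[m]], drop = FALSE])
            bound <- bound - sum(Nmat[, m] * lse)
        }
        dirphi <- sum(vapply(seq_len(M), function(m) {
            sum(vapply(gamma[[m]], dirichlet_elbo, 0, beta = beta))
        }, 0))
        elbo <- c(elbo, xlogz + bound + gauss + ent_eta + dirphi)
        ## coordinate ascent updates
        for (m in seq_len(M)) {
            for (f in seq_along(Xs[[m]])) {
                gamma[[m]][[f]] <- beta + gstat[[m]][[f]]
            }
        }
        par0 <- c(as.vector(Lambda), as.vector(log(Nu2)))
        opt <- stats::optim(par0, fn = eta_obj, gr = eta_grad,
            s = s, Nmat = Nmat, SigInv = SigInv, mu = mu,
            bstart = as.integer(bstart), bsize = as.integer(bsize),
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = innerMaxit, pgtol = 1e-6))
        Lambda <- matrix(opt$par[seq_len(D * Ktot)], D, Ktot)
        Nu2 <- exp(matrix(opt$par[D * Ktot + seq_len(D * Ktot)], D, Ktot))
        ## M-step for the shared Gaussian
        mu <- colMeans(Lambda)
        if (!fixSigma) {
            Ac <- sweep(Lambda, 2L, mu)
            Sigma <- crossprod(Ac) / D + diag(colMeans(Nu2), Ktot) +
                diag(ridge, Ktot)
            Sigma <- (Sigma + t(Sigma)) / 2
        }
        ## training predictive log-likelihood convergence check
        phis <- lapply(gamma, function(g) lapply(g, point_phi))
        thetas <- lapply(seq_len(M), function(m) {
            softmax_rows(Lambda[, blocks[[m]], drop = FALSE])
        })
        ll <- point_trainll(Xs, phis, thetas)
        if (!is.null(ll_prev)) {
            rel <- abs(ll - ll_prev) / pmax(abs(ll_prev), 1e-12)
            if (max(rel) < tol) {
                converged <- TRUE
                break
            }
        }
        ll_prev <- ll
    }
    list(model = "mmctm", K = K, blocks = blocks, gamma = gamma,
        Lambda = Lambda, Nu2 = Nu2, mu = mu, Sigma = Sigma, elbo = elbo,
        trainLL = ll, converged = converged, niter = length(elbo),
        beta = beta, fixSigma = fixSigma)
}

## hold signatures + prior fixed, update per-sample parameters only
mmctm_infer <- function(state, Xs, tol = 1e-6, maxIter = 200L) {
    K <- state$K
    blocks <- state$blocks
    M <- length(Xs)
    D <- nrow(Xs[[1L]][[1L]])
    Ktot <- sum(K)
    Nmat <- token_totals(Xs)
    Elogphi <- lapply(state$gamma, function(g) lapply(g, elog_dirichlet))
    SigInv <- chol2inv(chol(state$Sigma))
    mu <- state$mu
    Lambda <- matrix(mu, D, Ktot, byrow = TRUE)
    Nu2 <- matrix(1, D, Ktot)
    bstart <- vapply(blocks, function(b) b[1L] - 1L, 1L)
    lower <- c(rep(-30, D * Ktot), rep(-20, D * Ktot))
    upper <- c(rep(30, D * Ktot), rep(5, D * Ktot))
    obj_prev <- NULL
    for (it in seq_len(maxIter)) {
        s <- matrix(0, D, Ktot)
        for (m in seq_len(M)) {
            for (f in seq_along(Xs[[m]])) {
                r <- resp_stats(Xs[[m]][[f]], Elogphi[[m]][[f]],
                    Lambda[, blocks[[m]], drop = FALSE])
                s[, blocks[[m]]] <- s[, blocks[[m]]] + r$s
            }
        }
        par0 <- c(as.vector(Lambda), as.vector(log(Nu2)))
        opt <- stats::optim(par0, fn = eta_obj, gr = eta_grad,
            s = s, Nmat = Nmat, SigInv = SigInv, mu = mu,
            bstart = as.integer(bstart), bsize = as.integer(K),
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 100L, pgtol = 1e-6))
        Lambda <- matrix(opt$par[seq_len(D * Ktot)], D, Ktot)
        Nu2 <- exp(matrix(opt$par[D * Ktot + seq_len(D * Ktot)], D, Ktot))
        if (!is.null(obj_prev) &&
            abs(opt$value - obj_prev) < tol * max(abs(obj_prev), 1)) {
            break
        }
        obj_prev <- opt$value
    }
    lapply(seq_len(M), function(m) {
        softmax_rows(Lambda[, blocks[[m]], drop = FALSE])
    })
}

## ------------------------------------------------------------------ LDA --

lda_engine <- function(Xs1, K, alpha = 0.1, beta = 1, tol = 1e-5,
        maxIter = 1000L, seed = NULL, init = NULL) {
    ## Xs1: list of feature matrices for a single modality
    D <- nrow(Xs1[[1L]])
    N <- Reduce(`+`, lapply(Xs1, rowSums))
    if (!is.null(init)) {
        gamma <- init$gamma
        gtheta <- init$gtheta
    } else {
        if (!is.null(seed)) set.seed(seed)
        gamma <- lapply(Xs1, function(X) {
            matrix(as.double(sample.int(100L, K * ncol(X), replace = TRUE)),
                K, ncol(X))
        })
        gtheta <- matrix(alpha + N / K, D, K)
    }
    elbo <- numeric(0)
    ll_prev <- NULL
    ll <- NULL
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        Elogphi <- lapply(gamma, elog_dirichlet)
        Elogtheta <- elog_dirichlet(gtheta)
        s <- matrix(0, D, K)
        gstat <- vector("list", length(Xs1))
        xlogz <- 0
        for (f in seq_along(Xs1)) {
            r <- resp_stats(Xs1[[f]], Elogphi[[f]], Elogtheta)
            s <- s + r$s
            gstat[[f]] <- r$gstat
            xlogz <- xlogz + r$xlogz
        }
        dirphi <- sum(vapply(gamma, dirichlet_elbo, 0, beta = beta))
        dirtheta <- D * (lgamma(K * alpha) - K * lgamma(alpha)) +
            sum((alpha - 1) * Elogtheta) -
            sum(lgamma(rowSums(gtheta))) + sum(lgamma(gtheta)) -
            sum((gtheta - 1) * Elogtheta)
        elbo <- c(elbo, xlogz + dirphi + dirtheta)
        for (f in seq_along(Xs1)) gamma[[f]] <- beta + gstat[[f]]
        gtheta <- alpha + s
        phis <- lapply(gamma, point_phi)
        theta <- gtheta / rowSums(gtheta)
        ll <- point_trainll(list(Xs1), list(phis), list(theta))
        if (!is.null(ll_prev)) {
            rel <- abs(ll - ll_prev) / pmax(abs(ll_prev), 1e-12)
            if (max(rel) < tol) {
                converged <- TRUE
                break
            }
        }
        ll_prev <- ll
    }
    list(model = "lda", K = K, gamma = list(gamma), gtheta = gtheta,
        alpha = alpha, beta = beta, elbo = elbo, trainLL = ll,
        converged = converged, niter = length(elbo))
}

lda_infer <- function(state, Xs1, tol = 1e-8, maxIter = 200L) {
    K <- state$K
    D <- nrow(Xs1[[1L]])
    alpha <- state$alpha
    Elogphi <- lapply(state$gamma[[1L]], elog_dirichlet)
    N <- Reduce(`+`, lapply(Xs1, rowSums))
    gtheta <- matrix(alpha + N / K, D, K)
    for (it in seq_len(maxIter)) {
        Elogtheta <- elog_dirichlet(gtheta)
        s <- matrix(0, D, K)
        for (f in seq_along(Xs1)) {
            s <- s + resp_stats(Xs1[[f]], Elogphi[[f]], Elogtheta)$s
        }
        gnew <- alpha + s
        delta <- max(abs(gnew - gtheta) / pmax(abs(gtheta), 1e-12))
        gtheta <- gnew
        if (delta < tol) break
    }
    gtheta / rowSums(gtheta)
}
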