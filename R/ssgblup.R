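#' Covariance components of the multi-breed model
#'
#' Holds the t x t additive genetic covariance matrix across breeds-as-traits,
#' the per-breed permanent-environment variances (only breeds with repeated
#' records) and the per-breed residual variances.  Permanent-environment and
#' residual effects are uncorrelated between breeds because every animal
#' belongs to exactly one breed.
#'
#' @param Sigma_u symmetric positive-definite t x t genetic covariance
#'   matrix, dimnames = breed labels.
#' @param s2e named residual variances, one per breed.
#' @param s2p named permanent-environment variances for the repeated-record
#'   breeds (omit or `NA` for single-record breeds).
#' @return Object of class `covariance_components`.
#' @export
covariance_components <- function(Sigma_u, s2e, s2p = NULL) {
  Sigma_u <- as.matrix(Sigma_u)
  traits <- colnames(Sigma_u)
  if (is.null(traits)) stop("Sigma_u needs breed labels as dimnames")
  if (max(abs(Sigma_u - t(Sigma_u))) > 1e-10) stop("Sigma_u not symmetric")
  ev <- eigen(Sigma_u, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma_u is not positive definite")
  if (!all(traits %in% names(s2e))) stop("s2e must name every breed")
  s2e <- s2e[traits]
  if (any(!is.finite(s2e)) || any(s2e <= 0)) stop("residual variances must be > 0")
  if (!is.null(s2p)) {
    s2p <- s2p[!is.na(s2p)]
    if (!all(names(s2p) %in% traits)) stop("unknown breed in s2p")
    if (any(s2p <= 0)) stop("permanent-environment variances must be > 0")
  } else s2p <- stats::setNames(numeric(0), character(0))
  structure(list(Sigma_u = Sigma_u, s2e = s2e, s2p = s2p, traits = traits),
            class = "covariance_components")
}

#' Model specification for the breed-as-trait evaluation
#'
#' Each breed's tick phenotype is a separate trait.  Fixed effects per trait
#' are the contemporary-group factor plus optional covariates (zebu
#' fraction, expected heterozygosity, age linear and quadratic); the age
#' covariates are centered and scaled at design construction to keep the
#' quadratic term well-conditioned.  Identifiability: the design carries a
#' per-trait intercept and drops the first contemporary-group level of each
#' trait.
#'
#' @param traits ordered character vector of breed labels.
#' @param use_cg fit the contemporary-group factor (needs a `cg` column).
#' @param covariates subset of `c("zebu", "het", "age", "age2")` naming
#'   record columns to fit per trait (`age2` derives from `age`).
#' @param pe_traits breeds with repeated records, which carry a
#'   permanent-environment term.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(traits, use_cg = TRUE, covariates = character(),
                       pe_traits = character()) {
  if (length(covariates))
    covariates <- match.arg(covariates, c("zebu", "het", "age", "age2"),
                            several.ok = TRUE)
  if (!all(pe_traits %in% traits)) stop("pe_traits must be a subset of traits")
  if (anyDuplicated(traits)) stop("duplicated trait labels")
  structure(list(traits = traits, use_cg = use_cg,
                 covariates = if (length(covariates)) covariates else character(),
                 pe_traits = pe_traits),
            class = "model_spec")
}

# Build the sparse record x equation design matrix and the equation index.
# Equation order: fixed effects (trait-major), then additive effects
# animal-major (animal x trait), then permanent-environment levels grouped
# by trait.  Every equation belongs to exactly one trait.
build_design <- function(records, spec, animal_ids) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("animal", "breed", "value")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  T <- length(spec$traits)
  trait_of <- match(records$breed, spec$traits)
  if (anyNA(trait_of))
    stop("record breed(s) missing from the trait layout: ",
         paste(unique(records$breed[is.na(trait_of)]), collapse = ", "))
  anim_idx <- match(as.character(records$animal), as.character(animal_ids))
  if (anyNA(anim_idx))
    stop("record animal(s) not covered by the relationship matrix: ",
         paste(unique(records$animal[is.na(anim_idx)]), collapse = ", "))
  n_rec <- nrow(records)
  ti <- tj <- integer(0); tx <- numeric(0)
  index <- list()
  eq <- 0L
  add_col <- function(rows, vals, effect, trait, level) {
    eq <<- eq + 1L
    ti <<- c(ti, rows); tj <<- c(tj, rep.int(eq, length(rows)))
    tx <<- c(tx, vals)
    index[[eq]] <<- data.frame(eq = eq, effect = effect, trait = trait,
                               level = level)
  }
  for (t in seq_len(T)) {
    rows <- which(trait_of == t)
    lab <- spec$traits[t]
    add_col(rows, rep.int(1, length(rows)), "intercept", lab, "(Intercept)")
    if (spec$use_cg) {
      if (!"cg" %in% names(records)) stop("use_cg = TRUE but no `cg` column")
      lev <- sort(unique(as.character(records$cg[rows])))
      for (l in lev[-1]) # first level absorbed by the intercept
        add_col(rows[records$cg[rows] == l], rep.int(1, sum(records$cg[rows] == l)),
                "cg", lab, l)
    }
    for (cv in spec$covariates) {
      v <- if (cv == "age2") records$age[rows]^2 else records[[cv]][rows]
      if (is.null(v)) stop("covariate column missing: ", cv)
      if (cv %in% c("age", "age2")) v <- scale(v)[, 1]
      else v <- v - mean(v)
      if (all(!is.finite(v)) || stats::sd(v) == 0) next # constant: absorbed
      add_col(rows, v, "covariate", lab, cv)
    }
  }
  n_fix <- eq
  n_anim <- length(animal_ids)
  # additive: one design entry per record at eq n_fix + (a-1)*T + t
  ai <- seq_len(n_rec)
  aj <- n_fix + (anim_idx - 1L) * T + trait_of
  ti <- c(ti, ai); tj <- c(tj, aj); tx <- c(tx, rep.int(1, n_rec))
  anim_index <- data.frame(
    eq = n_fix + seq_len(n_anim * T),
    effect = "animal",
    trait = rep(spec$traits, times = n_anim),
    level = rep(as.character(animal_ids), each = T))
  eq <- n_fix + n_anim * T
  pe_index <- NULL
  pe_eqs <- integer(0)
  for (lab in spec$pe_traits) {
    t <- match(lab, spec$traits)
    rows <- which(trait_of == t)
    levs <- sort(unique(as.character(records$animal[rows])))
    for (l in levs) {
      eq <- eq + 1L
      rr <- rows[as.character(records$animal[rows]) == l]
      ti <- c(ti, rr); tj <- c(tj, rep.int(eq, length(rr)))
      tx <- c(tx, rep.int(1, length(rr)))
      pe_eqs <- c(pe_eqs, eq)
      pe_index <- rbind(pe_index,
                        data.frame(eq = eq, effect = "pe", trait = lab, level = l))
    }
  }
  W <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_rec, eq))
  index <- rbind(do.call(rbind, index), anim_index, pe_index)
  eq_trait <- match(index$trait, spec$traits)
  eq_type <- c(intercept = 0L, cg = 0L, covariate = 0L, animal = 1L,
               pe = 2L)[index$effect]
  list(W = W, y = records$value, rec_trait = trait_of,
       rec_animal = as.character(records$animal), index = index,
       eq_trait = eq_trait, eq_type = unname(eq_type), n_fix = n_fix,
       n_anim = n_anim, T = T, animal_ids = as.character(animal_ids),
       pe_eqs = pe_eqs)
}

#' Assemble the multi-trait single-step mixed-model equations
#'
#' Builds the sparse symmetric coefficient matrix and right-hand side of the
#' mixed-model equations: data cross-products weighted by the per-breed
#' residual variance, the additive block `H^-1 (x) Sigma_u^-1` over all
#' pedigree animals, and identity permanent-environment blocks scaled by the
#' per-breed PE variance.
#'
#' @param records phenotype data frame (`animal`, `breed`, `value`, plus the
#'   columns the [model_spec()] asks for).
#' @param spec a [model_spec()].
#' @param comps a [covariance_components()].
#' @param H_inv a [relmat()] of flavor `"H_inv"` or `"A_inv"` covering every
#'   animal in records and pedigree.
#' @return Object of class `mme_system`: `C`, `rhs`, `index`, plus the
#'   design pieces needed by the solver and by downstream adjustment.
#' @export
assemble_mme <- function(records, spec, comps, H_inv) {
  stopifnot(inherits(comps, "covariance_components"),
            inherits(H_inv, "relmat"))
  if (!setequal(spec$traits, comps$traits) ||
      !all(spec$traits == comps$traits))
    stop("model traits and covariance components disagree")
  if (!all(spec$pe_traits %in% names(comps$s2p)))
    stop("PE trait(s) without a PE variance: ",
         paste(setdiff(spec$pe_traits, names(comps$s2p)), collapse = ", "))
  ds <- build_design(records, spec, H_inv$ids)
  w <- 1 / comps$s2e[ds$rec_trait]
  C_data <- Matrix::crossprod(ds$W * sqrt(w))
  rhs <- as.numeric(Matrix::crossprod(ds$W, w * ds$y))
  Sigma_inv <- chol2inv(chol(comps$Sigma_u))
  C_add <- Matrix::kronecker(Matrix::Matrix(H_inv$mat, sparse = TRUE),
                             Sigma_inv)
  pe_d <- if (length(ds$pe_eqs))
    1 / comps$s2p[ds$index$trait[ds$pe_eqs]] else numeric(0)
  C <- C_data +
    Matrix::bdiag(Matrix::Diagonal(ds$n_fix, 0), C_add,
                  Matrix::Diagonal(length(pe_d), pe_d))
  structure(c(list(C = methods::as(C, "generalMatrix"), rhs = rhs,
                   spec = spec, comps = comps), ds),
            class = "mme_system")
}

#' Solve mixed-model equations by preconditioned conjugate gradients
#'
#' Jacobi (diagonal) preconditioning; deterministic given the system.  Fails
#' loudly (with the residual trace) rather than returning a silent partial
#' answer if the relative residual has not reached `tol` at `max_iter`.
#'
#' @param sys an [assemble_mme()] system.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap.
#' @return List of class `mme_solution`: `solutions` (index + estimate),
#'   `x`, `iterations`, `rel_residual`.
#' @export
solve_mme <- function(sys, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(sys, "mme_system"), tol > 0)
  C <- sys$C
  b <- sys$rhs
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    x <- numeric(length(b))
  } else {
    Minv <- 1 / Matrix::diag(C)
    x <- numeric(length(b))
    r <- b
    z <- Minv * r
    p <- z
    rz <- sum(r * z)
    trace <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      Cp <- as.numeric(C %*% p)
      alpha <- rz / sum(p * Cp)
      x <- x + alpha * p
      r <- r - alpha * Cp
      rel <- sqrt(sum(r^2)) / nb
      trace <- c(trace, rel)
      if (rel <= tol) break
      if (it >= max_iter)
        stop("PCG did not converge in ", max_iter, " iterations; ",
             "last residuals: ",
             paste(format(utils::tail(trace, 5), digits = 3), collapse = ", "))
      z <- Minv * r
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      p <- z + beta * p
    }
  }
  sol <- sys$index
  sol$estimate <- x[sol$eq]
  structure(list(solutions = sol, x = x,
                 iterations = if (nb == 0) 0L else it,
                 rel_residual = if (nb == 0) 0 else rel),
            class = "mme_solution")
}

#' Extract estimated breeding values from a solution
#'
#' @param solution an [solve_mme()] result.
#' @param sys the system it solved.
#' @return Matrix animals x traits of breeding values.
#' @export
extract_ebv <- function(solution, sys) {
  u <- solution$x[sys$n_fix + seq_len(sys$n_anim * sys$T)]
  matrix(u, nrow = sys$n_anim, ncol = sys$T, byrow = TRUE,
         dimnames = list(sys$animal_ids, sys$spec$traits))
}

#' Phenotypes adjusted for fixed and permanent-environment effects
#'
#' Computes `y* = y - X beta - W p` from a fitted system and averages over
#' an animal's repeated records, giving the adjusted phenotype used as the
#' realised-performance benchmark in validation.
#'
#' @param solution an [solve_mme()] result from the whole-data fit.
#' @param sys the system it solved.
#' @return Named vector of per-animal mean adjusted phenotypes.
#' @export
adjusted_phenotypes <- function(solution, sys) {
  fp <- sys$eq_type != 1L # fixed + permanent environment columns
  fit <- as.numeric(sys$W[, fp, drop = FALSE] %*% solution$x[fp])
  ystar <- sys$y - fit
  out <- tapply(ystar, sys$rec_animal, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Univariate single-step prediction for one breed
#'
#' Fits the marginal single-breed model implied by the multi-trait
#' specification, using that breed's marginal variances from the shared
#' covariance components so that uni- and multivariate predictions have
#' equivalent dispersion.
#'
#' @param records phenotype records of the target breed only (or a larger
#'   table; rows of other breeds are dropped).
#' @param spec the multi-trait [model_spec()].
#' @param comps the shared [covariance_components()].
#' @param H_inv relationship inverse as in [assemble_mme()].
#' @param breed target breed label.
#' @param tol,max_iter solver settings.
#' @return List: `solution`, `sys` (both univariate).
#' @export
predict_univariate <- function(records, spec, comps, H_inv, breed,
                               tol = 1e-10, max_iter = 10000L) {
  if (!breed %in% comps$traits) stop("breed absent from covariance components")
  rec <- records[records$breed == breed, , drop = FALSE]
  spec1 <- model_spec(breed, use_cg = spec$use_cg,
                      covariates = spec$covariates,
                      pe_traits = intersect(spec$pe_traits, breed))
  s2p1 <- comps$s2p[intersect(names(comps$s2p), breed)]
  comps1 <- covariance_components(
    Sigma_u = comps$Sigma_u[breed, breed, drop = FALSE],
    s2e = comps$s2e[breed],
    s2p = if (length(s2p1)) s2p1 else NULL)
  sys <- assemble_mme(rec, spec1, comps1, H_inv)
  list(solution = solve_mme(sys, tol, max_iter), sys = sys)
}
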