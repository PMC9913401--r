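## B-spline bases, tensor products and difference penalties for the
## penalized excess-hazard model.

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

## cubic B-spline margin with clamped boundary knots
make_margin <- function(x, n_interior, boundary = NULL, label = "x") {
  if (is.null(boundary)) boundary <- range(x)
  interior <- if (n_interior > 0)
    unname(stats::quantile(x, probs = seq_len(n_interior) / (n_interior + 1),
                           type = 7))
  else numeric(0)
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  knots <- c(rep(boundary[1], 4), sort(interior), rep(boundary[2], 4))
  list(knots = knots, boundary = boundary, K = length(interior) + 4L,
       label = label)
}

## margin with explicitly supplied interior knots
make_margin_knots <- function(interior, boundary, label = "x") {
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  knots <- c(rep(boundary[1], 4), sort(interior), rep(boundary[2], 4))
  list(knots = knots, boundary = boundary, K = length(interior) + 4L,
       label = label)
}

eval_margin <- function(margin, x, warn_extrapolate = TRUE) {
  b <- margin$boundary
  out <- x < b[1] - 1e-9 | x > b[2] + 1e-9
  if (any(out) && warn_extrapolate)
    warning(sum(out), " value(s) of ", margin$label,
            " outside the basis support [", format(b[1]), ", ", format(b[2]),
            "]; clamped")
  x <- pmin(pmax(x, b[1]), b[2])
  splines::splineDesign(margin$knots, x, ord = 4)
}

## second-order difference penalty, Frobenius-normalized
diff_penalty <- function(K) {
  D <- diff(diag(K), differences = min(2L, K - 1L))
  S <- crossprod(D)
  S / sqrt(sum(S^2))
}

## orthonormal complement of the constant coefficient direction; removes the
## constant function from a B-spline span (partition of unity)
constraint_Z <- function(K) {
  qr.Q(qr(matrix(1, K, 1)), complete = TRUE)[, -1, drop = FALSE]
}

## row-wise tensor (Kronecker) product
rowten <- function(A, B) {
  ka <- ncol(A); kb <- ncol(B)
  A[, rep(seq_len(ka), each = kb), drop = FALSE] *
    B[, rep(seq_len(kb), times = ka), drop = FALSE]
}

#' Basis configuration for the penalized excess-hazard model
#'
#' Cubic B-spline marginal bases: follow-up time with interior knots
#' `time_knots` on `[0, t_trunc]`; age and EDI with `age_df`/`edi_df`
#' quantile-placed interior knots on the observed range.  The three-way
#' tensor of form 4 uses its own (smaller) marginal dimensions
#' `form4_interior` to keep the tensor tractable.  Each tensor block carries
#' second-order difference penalties per margin; by default the margins of a
#' block share one smoothing multiplier (`tie_margins = FALSE` frees them).
#'
#' @param time_knots interior knots (years) of the follow-up time basis.
#' @param t_trunc follow-up truncation for modelling (years); also the upper
#'   boundary knot of the time basis.
#' @param age_df,edi_df number of interior quantile knots for the age and
#'   EDI margins.
#' @param edi_linear if `TRUE`, the proportional deprivation effect of
#'   form 2 (and the time-varying coefficient of form 3) is linear in the
#'   EDI score instead of a spline.
#' @param form4_interior interior-knot counts `c(time, age, edi)` of the
#'   three-way tensor margins.
#' @param gl_nodes Gauss-Legendre nodes per inter-knot piece for the per-subject cumulative
#'   excess hazard.
#' @param tie_margins share one smoothing multiplier across the margins of
#'   each penalty block.
#' @param grid_log10 coarse log10 smoothing grid searched per multiplier
#'   (refined locally to 0.5 resolution).
#' @return List of class `excess_basis_config`.
#' @export
excess_basis_config <- function(time_knots = c(0.5, 2), t_trunc = 6,
                                age_df = 1, edi_df = 1, edi_linear = FALSE,
                                form4_interior = c(0, 0, 0),
                                gl_nodes = 6, tie_margins = TRUE,
                                grid_log10 = seq(-2, 6, by = 2)) {
  structure(list(time_knots = time_knots, t_trunc = t_trunc,
                 age_df = age_df, edi_df = edi_df, edi_linear = edi_linear,
                 form4_interior = form4_interior, gl_nodes = gl_nodes,
                 tie_margins = tie_margins, grid_log10 = grid_log10),
            class = "excess_basis_config")
}

## Build the model specification (margins + block layout) from the data.
build_spec <- function(form, t, age, edi, config) {
  stopifnot(form %in% 1:4)
  m <- list(
    t = make_margin_knots(config$time_knots, c(0, config$t_trunc), "time"),
    age = make_margin(age, config$age_df, label = "age"),
    edi = make_margin(edi, config$edi_df, label = "EDI")
  )
  if (form == 4) {
    f4 <- config$form4_interior
    m$t4 <- make_margin_knots(
      if (f4[1] > 0) stats::quantile(t, seq_len(f4[1]) / (f4[1] + 1)) else numeric(0),
      c(0, config$t_trunc), "time")
    m$age4 <- make_margin(age, f4[2], label = "age")
    m$edi4 <- make_margin(edi, f4[3], label = "EDI")
  }
  blocks <- switch(form,
    list(list(name = "baseline", margins = c("t", "age"),
              constrain = c(FALSE, FALSE))),
    list(list(name = "baseline", margins = c("t", "age"),
              constrain = c(FALSE, FALSE)),
         list(name = "edi", margins = "edi", constrain = TRUE)),
    list(list(name = "baseline", margins = c("t", "age"),
              constrain = c(FALSE, FALSE)),
         list(name = "t_edi", margins = c("t", "edi"),
              constrain = c(FALSE, TRUE))),
    list(list(name = "t_age_edi", margins = c("t4", "age4", "edi4"),
              constrain = c(FALSE, FALSE, FALSE)))
  )
  list(form = form, margins = m, blocks = blocks,
       edi_linear = isTRUE(config$edi_linear),
       edi_center = stats::median(edi))
}

## Design matrix columns of one margin inside a block (with constraint /
## linear-EDI handling).
margin_cols <- function(spec, mname, constrain, x, warn = TRUE) {
  if (spec$edi_linear && mname %in% c("edi", "edi4") && constrain) {
    return(matrix(x - spec$edi_center, ncol = 1))
  }
  M <- eval_margin(spec$margins[[mname]], x, warn_extrapolate = warn)
  if (constrain) M <- M %*% constraint_Z(ncol(M))
  M
}

## Full design matrix at (t, age, edi).
build_design <- function(spec, t, age, edi, warn = TRUE) {
  vals <- list(t = t, t4 = t, age = age, age4 = age, edi = edi, edi4 = edi)
  do.call(cbind, lapply(spec$blocks, function(b) {
    mats <- Map(function(mn, cz) margin_cols(spec, mn, cz, vals[[mn]], warn),
                b$margins, b$constrain)
    Reduce(rowten, mats)
  }))
}

## Penalty matrices (full p x p), one per margin per block, plus the
## smoothing-group index (per block when tied, per margin otherwise).
build_penalties <- function(spec, tie_margins = TRUE) {
  ## column count per block
  bk <- vapply(spec$blocks, function(b) {
    as.integer(prod(vapply(seq_along(b$margins), function(j) {
      mn <- b$margins[j]
      if (spec$edi_linear && mn %in% c("edi", "edi4") && b$constrain[j])
        return(1L)
      K <- spec$margins[[mn]]$K
      if (b$constrain[j]) K - 1L else K
    }, integer(1))))
  }, integer(1))
  p <- sum(bk)
  offs <- cumsum(c(0, bk))
  pens <- list(); groups <- integer(0); gi <- 0
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    dims <- vapply(seq_along(b$margins), function(j) {
      mn <- b$margins[j]
      if (spec$edi_linear && mn %in% c("edi", "edi4") && b$constrain[j])
        return(1L)
      K <- spec$margins[[mn]]$K
      if (b$constrain[j]) K - 1L else K
    }, integer(1))
    gi <- gi + 1
    for (j in seq_along(b$margins)) {
      mn <- b$margins[j]
      if (spec$edi_linear && mn %in% c("edi", "edi4") && b$constrain[j])
        next                      # a linear term carries no curvature penalty
      K <- spec$margins[[mn]]$K
      Sj <- diff_penalty(K)
      if (b$constrain[j]) {
        Z <- constraint_Z(K)
        Sj <- t(Z) %*% Sj %*% Z
      }
      ## Kronecker expansion over the block's margins (row-major order used
      ## by rowten: first margin varies slowest)
      mats <- lapply(seq_along(dims), function(l)
        if (l == j) Sj else diag(dims[l]))
      Sfull_b <- Reduce(`%x%`, mats)
      S <- matrix(0, p, p)
      ii <- (offs[bi] + 1):(offs[bi] + bk[bi])
      S[ii, ii] <- Sfull_b
      pens[[length(pens) + 1]] <- S
      groups <- c(groups, if (tie_margins) gi else length(pens))
    }
  }
  ## renumber groups consecutively
  groups <- match(groups, unique(groups))
  list(pens = pens, groups = groups, p = p, block_cols = bk, offsets = offs)
}
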