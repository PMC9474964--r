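#' Lawson-Hanson nonnegative least squares
#'
#' Solves min ||A x - b||_2 subject to x >= 0 by the Lawson-Hanson
#' active-set algorithm, the solver classically used for linearized
#' compartment-model parametric imaging.
#'
#' @param A Design matrix (m x n).
#' @param b Response vector (length m).
#' @param tol Dual-feasibility tolerance (default relative to `A`).
#' @return List with `x` (solution), `residual_norm`, and `passive`
#'   (indices of unconstrained coefficients).
#' @export
nnls_lh <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m) stop("dimensions of A and b disagree")
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n)
  x <- numeric(n)
  P <- rep(FALSE, n)                    # passive (free) set
  w <- crossprod(A, b - A %*% x)        # dual vector
  iter <- 0L
  max_iter <- 3L * n * 10L
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- tryCatch(qr.solve(Ap, b), error = function(e) {
        as.numeric(MASS_ginv(crossprod(Ap)) %*% crossprod(Ap, b))
      })
      if (all(s[P] > tol)) break
      qset <- P & s <= tol
      alpha <- min(x[qset] / (x[qset] - s[qset]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  list(x = as.numeric(x), residual_norm = sqrt(sum((b - A %*% x)^2)),
       passive = which(P))
}

# Moore-Penrose pseudoinverse via SVD; fallback for rank-deficient passive
# sets inside the NNLS iteration.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Basis terms of the linearized irreversible 2T3k model
#'
#' The nonlinear compartment fit can be reformed into a linear model
#' C_T(t) = P1 C_p(t) + P2 int C_p + P3 iint C_p + P4 int C_T + P5 iint C_T.
#' In irreversible mode (k4 = 0) P5 = 0 and P4 = -theta4 with theta4 >= 0.
#' This builds the design terms at the frame midpoints; input-function
#' integrals are cumulative trapezoids on the (fine) input grid, tissue
#' integrals cumulative trapezoids on the midpoint grid anchored at
#' C_T(0) = 0.
#'
#' @param tac A `pet_tac` (supplies the schedule and tissue curve).
#' @param input_fn A `pet_if`.
#' @return A tibble with columns `t`, `cp`, `icp`, `iicp`, `ict`, `iict`.
#' @export
linearized_basis <- function(tac, input_fn) {
  mid <- frame_mid(tac)
  g <- if_nodes(input_fn)
  tt <- sort(unique(c(g$t, mid)))
  vv <- stats::approx(g$t, g$v, xout = tt, rule = 2)$y
  icp_g <- cumtrapz(tt, vv)
  iicp_g <- cumtrapz(tt, icp_g)
  idx <- match(round(mid, 12), round(tt, 12))
  tis <- tissue_integrals(mid, tac$value)
  tibble::tibble(t = mid,
                 cp = vv[idx], icp = icp_g[idx], iicp = iicp_g[idx],
                 ict = tis$ict, iict = tis$iict)
}

cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

tissue_integrals <- function(mid, values) {
  t0 <- c(0, mid)
  v0 <- c(0, values)
  ict <- cumtrapz(t0, v0)
  iict <- cumtrapz(t0, ict)
  list(ict = ict[-1], iict = iict[-1])
}

#' Voxel-wise linearized 2T3k estimation by NNLS
#'
#' Solves C_T = P1 C_p + P2 int C_p + P3 iint C_p - theta4 int C_T with all
#' coefficients nonnegative (the int C_T column is negated so Lawson-Hanson
#' applies), then maps back to micro-parameters:
#' Vb = P1, theta4 = k2 + k3, K1 = (P2 - P1 theta4)/(1 - P1),
#' k3 = P3 / ((1 - P1) K1), k2 = theta4 - k3, and
#' Ki = P3 / ((1 - P1) theta4). Degenerate voxels (P1 >= 1, K1 <= 0,
#' theta4 = 0, or k3 > theta4 requiring clipping) are returned as zeros or
#' clipped values with a flag rather than errors, so voxel loops never stop.
#'
#' @param basis Tibble from [linearized_basis()].
#' @param values Tissue activity values at the same frames as `basis`.
#' @return A list with `coeffs` (tibble P1, P2, P3, theta4), `params`
#'   (a `kinetic_params` row), and `flag` (`"ok"`, `"clipped"`,
#'   `"degenerate"`, `"zero"`).
#' @export
nnls_2t3k_voxel <- function(basis, values) {
  if (length(values) != nrow(basis)) stop("basis and values must align")
  if (all(values == 0)) {
    return(list(coeffs = tibble::tibble(P1 = 0, P2 = 0, P3 = 0, theta4 = 0),
                params = kinetic_params(0, 0, 0, 0), flag = "zero"))
  }
  A <- cbind(basis$cp, basis$icp, basis$iicp, -basis$ict)
  sol <- nnls_lh(A, values)
  P1 <- sol$x[1]; P2 <- sol$x[2]; P3 <- sol$x[3]; theta4 <- sol$x[4]
  coeffs <- tibble::tibble(P1 = P1, P2 = P2, P3 = P3, theta4 = theta4)
  flag <- "ok"
  if (P1 >= 1 || theta4 <= 0) {
    K1 <- if (P1 < 1) max(P2 - P1 * theta4, 0) / (1 - P1) else 0
    if (theta4 <= 0 && K1 > 0) {
      # pure trapping limit: all influx is retained, Ki = K1
      params <- kinetic_params(min(K1, 5), 0, 0, min(max(P1, 0), 1))
      return(list(coeffs = coeffs, params = params, flag = "clipped"))
    }
    return(list(coeffs = coeffs, params = kinetic_params(0, 0, 0, 0),
                flag = "degenerate"))
  }
  K1 <- (P2 - P1 * theta4) / (1 - P1)
  if (K1 <= 0) {
    return(list(coeffs = coeffs, params = kinetic_params(0, 0, 0, min(P1, 1)),
                flag = "degenerate"))
  }
  k3 <- P3 / ((1 - P1) * K1)
  if (k3 > theta4) {
    k3 <- theta4
    flag <- "clipped"
  }
  k2 <- theta4 - k3
  params <- kinetic_params(min(K1, 5), min(k2, 5), min(k3, 5), P1)
  list(coeffs = coeffs, params = params, flag = flag)
}

#' Voxel-wise parametric images
#'
#' Applies the linearized NNLS 2T3k estimator (or Patlak graphical
#' analysis) to every voxel (optionally inside a mask) of a dynamic image,
#' producing K1, k2, k3, Vb and Ki maps (Ki only, for Patlak). The Ki map
#' is recomputed from the micro-parameter maps via Ki = K1 k3/(k2 + k3).
#' Patlak mode uses the frames in \[t_star, end\] (default 30-60 min).
#'
#' @param image A `dynamic_image`.
#' @param input_fn A `pet_if` spanning the schedule.
#' @param method `"nnls"` (default) or `"patlak"`.
#' @param mask Optional logical 3D array restricting the fit.
#' @param t_star Patlak equilibrium time, minutes.
#' @return A `parametric_maps` object: list of 3D arrays in `$maps`
#'   (K1, k2, k3, Vb, Ki for NNLS; Ki, intercept for Patlak), a `flags`
#'   character array, the schedule and voxel size.
#' @export
fit_parametric_images <- function(image, input_fn, method = c("nnls", "patlak"),
                                  mask = NULL, t_star = 30) {
  method <- match.arg(method)
  stopifnot(inherits(image, "dynamic_image"))
  dims <- dim(image$data)[1:3]
  nframe <- dim(image$data)[4]
  if (max(image$schedule$end) > max(if_nodes(input_fn)$t) + 1e-6) {
    stop("input function must span the acquisition")
  }
  if (is.null(mask)) mask <- array(TRUE, dims)
  vox <- which(as.vector(mask))
  flat <- matrix(image$data, ncol = nframe)
  mid <- frame_mid(image$schedule)

  zero_map <- function() array(0, dims)
  flags <- array("skipped", dims)

  if (method == "nnls") {
    template <- tac(image$schedule, rep(0, nframe))
    ## Cp-derived basis columns are voxel-independent; tissue integrals are not
    base <- linearized_basis(template, input_fn)
    maps <- list(K1 = zero_map(), k2 = zero_map(), k3 = zero_map(),
                 Vb = zero_map(), Ki = zero_map())
    for (v in vox) {
      y <- flat[v, ]
      tis <- tissue_integrals(mid, y)
      b <- base
      b$ict <- tis$ict; b$iict <- tis$iict
      res <- nnls_2t3k_voxel(b, y)
      maps$K1[v] <- res$params$K1
      maps$k2[v] <- res$params$k2
      maps$k3[v] <- res$params$k3
      maps$Vb[v] <- res$params$Vb
      flags[v] <- res$flag
    }
    theta <- maps$k2 + maps$k3
    maps$Ki <- ifelse(theta > 0, maps$K1 * maps$k3 / theta, 0)
    dim(maps$Ki) <- dims
  } else {
    sel <- mid >= t_star
    if (sum(sel) < 2) stop("need at least 2 frames beyond t*")
    cp <- if_value(input_fn, mid[sel])
    x <- if_cumint(input_fn, mid[sel]) / cp
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    maps <- list(Ki = zero_map(), intercept = zero_map())
    for (v in vox) {
      y <- flat[v, sel] / cp
      slope <- sum(xc * y) / sxx
      maps$Ki[v] <- max(slope, 0)
      maps$intercept[v] <- mean(y) - slope * mean(x)
      flags[v] <- if (slope >= 0) "ok" else "clipped"
    }
  }
  structure(list(maps = maps, flags = flags, method = method,
                 schedule = image$schedule,
                 voxel_size_mm = image$voxel_size_mm),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("parametric_maps (%s): %s; %d voxels fitted\n", x$method,
              paste(names(x$maps), collapse = ", "),
              sum(x$flags != "skipped")))
  invisible(x)
}

#' Coefficient of variation over an ROI
#'
#' CoV = SD / mean of the map values inside the mask; the standard map
#' noise metric. Population SD (divisor n) by default.
#'
#' @param volume 3D numeric array (one parametric map).
#' @param mask Logical 3D array.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The coefficient of variation (dimensionless).
#' @export
roi_cov <- function(volume, mask, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  vals <- volume[as.logical(mask)]
  if (length(vals) == 0) stop("mask is empty")
  m <- mean(vals)
  if (m == 0) stop("ROI mean is zero; CoV undefined")
  s <- stats::sd(vals)
  if (sd_type == "population") s <- s * sqrt((length(vals) - 1) / length(vals))
  s / m
}
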