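## Synthetic co-registered multimodal biopsy phantom.
##
## Geometry primitives are deliberately simple and seed-reproducible:
## adipose lobules and carcinoma foci are overlapping random spheres, ducts
## and vessels are random-walk tubes. Optical fluence decay is a single
## exponential in depth; the PAT point spread is a fixed anisotropic
## Gaussian. No acoustic or optical transport is simulated.

.NUCLEUS_SIGMA_MM <- 0.008

## Stamp a sphere into a label volume where the current label is in `where`.
## Returns list(labels, n) with the number of voxels changed.
.stamp_sphere <- function(labels, coords, center, radius, value, where) {
  rng <- lapply(1:3, function(ax)
    which(abs(coords[[ax]] - center[ax]) <= radius))
  if (any(lengths(rng) == 0L)) return(list(labels = labels, n = 0L))
  sub <- labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  d2 <- outer(outer((coords[[1]][rng[[1]]] - center[1])^2,
                    (coords[[2]][rng[[2]]] - center[2])^2, "+"),
              (coords[[3]][rng[[3]]] - center[3])^2, "+")
  sel <- d2 <= radius^2 & array(sub %in% where, dim(sub))
  n <- sum(sel)
  if (n > 0L) {
    sub[sel] <- value
    labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  list(labels = labels, n = n)
}

## Random-walk tube path inside the inner (margin-respecting) box.
.walk_path <- function(lo, hi, step, n_steps) {
  p <- runif(3, lo, hi)
  d <- rnorm(3); d <- d / sqrt(sum(d^2))
  path <- matrix(0, n_steps, 3)
  for (i in seq_len(n_steps)) {
    path[i, ] <- p
    d <- d + rnorm(3, sd = 0.35)
    d <- d / sqrt(sum(d^2))
    p2 <- p + step * d
    for (ax in 1:3) {
      if (p2[ax] < lo[ax] || p2[ax] > hi[ax]) {
        d[ax] <- -d[ax]
        p2[ax] <- min(max(p2[ax], lo[ax]), hi[ax])
      }
    }
    p <- p2
  }
  path
}

#' Generate a synthetic multimodal biopsy phantom
#'
#' Builds a ground-truth tissue volume (adipose lobules, fibrous stroma,
#' ducts with nuclei-dense walls, lipid-poor carcinoma foci, hemoglobin-rich
#' vessels) and renders the five imaging channels from both the anterior and
#' posterior side. The two sides view the same truth from opposite depth
#' directions and are each cropped to the configured imaging depth.
#'
#' All randomness derives from \code{params@seed}; a fixed seed gives
#' bit-identical output.
#'
#' @param params a \linkS4class{PhantomParams}.
#' @param sides which sides to render.
#' @param channels which channels to render (subset of \code{pat_lipid},
#'   \code{pat_hemoglobin}, \code{pat_off}, \code{ultrasound},
#'   \code{ispim_eosin}, \code{ispim_nuclei}).
#' @return A list with elements \code{truth} (\linkS4class{PhantomTruth}),
#'   one named list of \linkS4class{ChannelVolume}s per rendered side, and
#'   \code{params}.
#' @examples
#' ph <- generatePhantom(phantomParams(extentMM = c(1.5, 1, 1.5),
#'                                     ispimSpacingMM = rep(0.02, 3),
#'                                     seed = 1),
#'                       sides = "anterior", channels = "pat_lipid")
#' classFractions(ph$truth)
#' @export
generatePhantom <- function(params,
                            sides = c("anterior", "posterior"),
                            channels = c("pat_lipid", "pat_hemoglobin",
                                         "pat_off", "ultrasound",
                                         "ispim_eosin", "ispim_nuclei")) {
  stopifnot(is(params, "PhantomParams"))
  validObject(params)
  sides <- match.arg(sides, .SIDES, several.ok = TRUE)
  set.seed(params@seed)
  truth <- .build_truth(params)
  ## one sub-seed per (side, channel) so any render can be redone alone
  grid <- expand.grid(side = .SIDES,
                      channel = c("pat_lipid", "pat_hemoglobin", "pat_off",
                                  "ultrasound", "ispim_eosin",
                                  "ispim_nuclei"),
                      stringsAsFactors = FALSE)
  seeds <- .derive_seeds(params@seed + 1L, nrow(grid))
  out <- list(truth = truth, params = params)
  for (side in sides) {
    vols <- list()
    for (ch in channels) {
      sd_i <- seeds[grid$side == side & grid$channel == ch]
      vols[[ch]] <- switch(ch,
        pat_lipid = renderPATChannel(truth, "lipid", params, side, sd_i),
        pat_hemoglobin = renderPATChannel(truth, "hemoglobin", params, side,
                                          sd_i),
        pat_off = renderPATChannel(truth, "off_resonance", params, side,
                                   sd_i),
        ultrasound = renderUltrasound(truth, params, side, sd_i),
        ispim_eosin = renderISPIMChannels(truth, params, side,
                                          sd_i, which = "eosin"),
        ispim_nuclei = renderISPIMChannels(truth, params, side,
                                           sd_i, which = "nuclei"))
    }
    out[[side]] <- vols
  }
  out
}

## Build the ground-truth label/concentration volumes and nuclei set.
.build_truth <- function(params) {
  ext <- params@extentMM
  dx <- params@truthSpacingMM
  d <- .grid_dim(ext, dx)
  coords <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * dx[ax])
  cls <- .PHANTOM_CLASSES

  ## tissue block: margin along scan and lateral axes; full depth
  m <- params@marginMM
  tissue <- array(TRUE, d)
  tissue[coords[[1]] < m | coords[[1]] > ext[1] - m, , ] <- FALSE
  tissue[, , coords[[3]] < m | coords[[3]] > ext[3] - m] <- FALSE
  labels <- array(cls[["background"]], d)
  labels[tissue] <- cls[["stroma"]]
  n_tissue <- sum(tissue)
  lo <- pmax(c(m, 0, m), 0) + 1e-9
  hi <- ext - c(m, 0, m) - 1e-9
  inner <- hi - lo
  fr <- params@fractions

  ## feasibility: requested foci must fit the inner box
  if (fr[["carcinoma"]] > 0 && params@carcinomaFoci > 0L &&
      min(inner) <= 2 * params@carcinomaRadiusMM[1])
    stop("phantom extent too small to place the requested carcinoma foci",
         call. = FALSE)

  ## adipose: overlapping spheres until the target fraction is realized
  if (fr[["adipose"]] > 0) {
    target <- fr[["adipose"]] * n_tissue
    placed <- 0L
    for (i in seq_len(5000L)) {
      if (placed >= target) break
      ctr <- runif(3, lo, hi)
      r <- runif(1, params@adiposeRadiusMM[1], params@adiposeRadiusMM[2])
      st <- .stamp_sphere(labels, coords, ctr, r, cls[["adipose"]],
                          cls[["stroma"]])
      labels <- st$labels
      placed <- placed + st$n
    }
  }

  ## ducts: random-walk tubes, wall stamped first, lumen carved after
  if (fr[["duct"]] > 0 && params@ductCount > 0L) {
    r <- params@ductRadiusMM
    w <- params@ductWallMM
    len_total <- fr[["duct"]] * n_tissue * prod(dx) / (pi * (r + w)^2)
    step <- max(r / 2, dx[1])
    n_steps <- max(2L, ceiling(len_total / params@ductCount / step))
    for (k in seq_len(params@ductCount)) {
      path <- .walk_path(lo, hi, step, n_steps)
      for (i in seq_len(nrow(path)))
        labels <- .stamp_sphere(labels, coords, path[i, ], r + w,
                                cls[["duct_wall"]],
                                cls[c("stroma", "adipose")])$labels
      for (i in seq_len(nrow(path)))
        labels <- .stamp_sphere(labels, coords, path[i, ], r,
                                cls[["duct_lumen"]],
                                cls[["duct_wall"]])$labels
    }
  }

  ## vessels: thinner random-walk tubes
  if (fr[["vessel"]] > 0 && params@vesselCount > 0L) {
    r <- params@vesselRadiusMM
    len_total <- fr[["vessel"]] * n_tissue * prod(dx) / (pi * r^2)
    step <- max(r / 2, dx[1])
    n_steps <- max(2L, ceiling(len_total / params@vesselCount / step))
    for (k in seq_len(params@vesselCount)) {
      path <- .walk_path(lo, hi, step, n_steps)
      for (i in seq_len(nrow(path)))
        labels <- .stamp_sphere(labels, coords, path[i, ], r,
                                cls[["vessel"]],
                                cls[c("stroma", "adipose")])$labels
    }
  }

  ## carcinoma foci: equal-volume spheres hitting the target fraction
  if (fr[["carcinoma"]] > 0 && params@carcinomaFoci > 0L) {
    v_target <- fr[["carcinoma"]] * n_tissue * prod(dx)
    r <- (3 * v_target / params@carcinomaFoci / (4 * pi))^(1 / 3)
    r <- min(max(r, params@carcinomaRadiusMM[1]), params@carcinomaRadiusMM[2])
    for (k in seq_len(params@carcinomaFoci)) {
      ctr <- runif(3, pmin(lo + r, hi), pmax(hi - r, lo))
      labels <- .stamp_sphere(labels, coords, ctr, r, cls[["carcinoma"]],
                              cls[c("stroma", "adipose")])$labels
    }
  }

  ## chromophore maps
  lipid <- array(0, d)
  lipid[labels == cls[["adipose"]]] <- 1
  if (params@stromalLipidFraction > 0) {
    stroma_idx <- which(labels == cls[["stroma"]])
    n_sp <- round(params@stromalLipidFraction * length(stroma_idx))
    if (n_sp > 0)
      lipid[sample(stroma_idx, n_sp)] <- params@stromalLipidLevel
  }
  hgb <- array(0, d)
  hgb[labels == cls[["vessel"]]] <- 1

  ## nuclei point set: per-class stylized densities
  vox_mm3 <- prod(dx)
  pts <- list()
  for (cname in names(params@nucleiDensity)) {
    dens <- params@nucleiDensity[[cname]]
    if (dens <= 0 || !cname %in% names(cls)) next
    idx <- which(labels == cls[[cname]])
    n <- round(dens * length(idx) * vox_mm3)
    if (n < 1L || length(idx) == 0L) next
    pick <- sample(idx, n, replace = n > length(idx))
    ijk <- arrayInd(pick, d)
    xyz <- sweep(ijk - 0.5, 2, dx, `*`) +
      matrix(runif(3 * n, -0.49, 0.49), n, 3) %*% diag(dx)
    pts[[cname]] <- xyz
  }
  nuclei <- if (length(pts)) do.call(rbind, pts) else matrix(0, 0, 3)
  dimnames(nuclei) <- NULL

  new("PhantomTruth", labels = labels, lipid = lipid, hemoglobin = hgb,
      nuclei = nuclei, tissue = tissue, spacingMM = dx)
}

## Flip the depth axis (axis 2) of a 3D array.
.flip_depth <- function(arr) arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]

#' Render a PAT channel from phantom truth
#'
#' Signal is chromophore concentration attenuated by a single-exponential
#' fluence decay in depth, resampled to the PAT lattice, blurred by the
#' anisotropic PAT point spread, with additive Gaussian noise, clipped to be
#' non-negative. The off-resonance role renders from zero concentration
#' (noise only). For the posterior side the truth is viewed from the
#' opposite depth direction.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param role \code{"lipid"} (1210 nm), \code{"hemoglobin"} (1100 nm) or
#'   \code{"off_resonance"} (1400 nm control).
#' @param params a \linkS4class{PhantomParams}.
#' @param side acquisition side.
#' @param seed optional seed for the noise draw (restores RNG state).
#' @return A \linkS4class{ChannelVolume}.
#' @export
renderPATChannel <- function(truth, role = c("lipid", "hemoglobin",
                                             "off_resonance"),
                             params, side = "anterior", seed = NULL) {
  role <- match.arg(role)
  side <- match.arg(side, .SIDES)
  conc <- switch(role, lipid = truth@lipid, hemoglobin = truth@hemoglobin,
                 off_resonance = array(0, dim(truth@labels)))
  if (side == "posterior") conc <- .flip_depth(conc)
  dz <- truth@spacingMM[2]
  depth <- (seq_len(dim(conc)[2]) - 0.5) * dz
  att <- exp(-depth / params@fluenceDecayMM)
  conc <- sweep(conc, 2, att, `*`)

  ext <- dim(conc) * truth@spacingMM
  d_pat <- .grid_dim(ext, params@patSpacingMM)
  img <- .resample3(conc, truth@spacingMM, params@patSpacingMM, d_pat)
  img <- .gauss_blur3(img, params@patBlurSigmaMM / params@patSpacingMM)

  chan <- switch(role, lipid = "pat_lipid", hemoglobin = "pat_hemoglobin",
                 off_resonance = "pat_off")
  wl <- switch(role, lipid = 1210, hemoglobin = 1100, off_resonance = 1400)
  sd_n <- params@noiseSD[[chan]]
  img <- .with_seed(seed, {
    if (sd_n > 0) img <- img + array(rnorm(length(img), sd = sd_n), dim(img))
    img
  })
  img[img < 0] <- 0
  channelVolume(img, params@patSpacingMM, chan, side, wavelengthNM = wl)
}

#' Render the light-sheet (iSPIM) channels from phantom truth
#'
#' The eosin channel is bright in stroma and duct walls and dim in adipose
#' tissue (lipid displaces the eosinophilic matrix); the nuclei channel is a
#' sum of Gaussian spots at the truth nuclei positions. Both optionally
#' carry a periodic multiplicative stripe emulating stitching seams, plus
#' additive Gaussian noise.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param params a \linkS4class{PhantomParams}.
#' @param side acquisition side.
#' @param seed optional seed for the noise draw.
#' @param which \code{"eosin"}, \code{"nuclei"} or \code{"both"}.
#' @return A \linkS4class{ChannelVolume}, or a list of the two when
#'   \code{which = "both"}.
#' @export
renderISPIMChannels <- function(truth, params, side = "anterior",
                                seed = NULL, which = c("both", "eosin",
                                                       "nuclei")) {
  which <- match.arg(which)
  side <- match.arg(side, .SIDES)
  cls <- .PHANTOM_CLASSES
  dx <- params@ispimSpacingMM
  ext <- dim(truth@labels) * truth@spacingMM
  d_isp <- .grid_dim(ext, dx)

  seeds <- if (is.null(seed)) c(NA, NA) else .derive_seeds(seed, 2L)
  finish <- function(img, chan, seed_i) {
    if (params@stripeAmplitude > 0) {
      lat <- (seq_len(dim(img)[3]) - 0.5) * dx[3]
      stripe <- 1 + params@stripeAmplitude *
        sin(2 * pi * lat / params@stripePeriodMM)
      img <- sweep(img, 3, stripe, `*`)
    }
    sd_n <- params@noiseSD[[chan]]
    img <- .with_seed(if (is.na(seed_i)) NULL else seed_i, {
      if (sd_n > 0)
        img <- img + array(rnorm(length(img), sd = sd_n), dim(img))
      img
    })
    img[img < 0] <- 0
    channelVolume(img, dx, chan, side,
                  wavelengthNM = if (chan == "ispim_eosin") 488 else 647)
  }

  out <- list()
  if (which %in% c("both", "eosin")) {
    levels <- c(0, 0.15, 0.8, 0.05, 0.9, 0.85, 0.5)  # by class code 0..6
    lab <- truth@labels
    if (side == "posterior") lab <- .flip_depth(lab)
    lab <- .resample3_nn(lab, truth@spacingMM, dx, d_isp)
    img <- array(levels[lab + 1L], dim(lab))
    out$eosin <- finish(img, "ispim_eosin", seeds[1])
  }
  if (which %in% c("both", "nuclei")) {
    img <- array(0, d_isp)
    pts <- truth@nuclei
    if (nrow(pts) > 0) {
      if (side == "posterior") pts[, 2] <- ext[2] - pts[, 2]
      sig <- .NUCLEUS_SIGMA_MM
      rad <- ceiling(3 * sig / dx)
      for (p in seq_len(nrow(pts))) {
        ctr <- pts[p, ]
        ijk <- pmin(d_isp, pmax(1L, floor(ctr / dx) + 1L))
        i1 <- max(1L, ijk[1] - rad[1]):min(d_isp[1], ijk[1] + rad[1])
        i2 <- max(1L, ijk[2] - rad[2]):min(d_isp[2], ijk[2] + rad[2])
        i3 <- max(1L, ijk[3] - rad[3]):min(d_isp[3], ijk[3] + rad[3])
        d2 <- outer(outer(((i1 - 0.5) * dx[1] - ctr[1])^2,
                          ((i2 - 0.5) * dx[2] - ctr[2])^2, "+"),
                    ((i3 - 0.5) * dx[3] - ctr[3])^2, "+")
        img[i1, i2, i3] <- img[i1, i2, i3] + exp(-d2 / (2 * sig^2))
      }
    }
    out$nuclei <- finish(img, "ispim_nuclei", seeds[2])
  }
  if (which == "both") out else out[[which]]
}

#' Render the ultrasound channel from phantom truth
#'
#' Multiplicative speckle over a class-dependent echogenicity map. Duct
#' lumina are hypoechoic; background is zero. The channel is used for
#' tissue-mask construction and visual co-registration only, never for
#' scoring.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param params a \linkS4class{PhantomParams}; the \code{ultrasound} entry
#'   of \code{noiseSD} is the speckle variance (0 disables speckle).
#' @param side acquisition side.
#' @param seed optional seed for the speckle draw.
#' @return A \linkS4class{ChannelVolume}.
#' @export
renderUltrasound <- function(truth, params, side = "anterior", seed = NULL) {
  side <- match.arg(side, .SIDES)
  echo <- c(0, 0.8, 0.6, 0.05, 0.55, 0.5, 0.3)  # by class code 0..6
  lab <- truth@labels
  if (side == "posterior") lab <- .flip_depth(lab)
  ext <- dim(lab) * truth@spacingMM
  d_pat <- .grid_dim(ext, params@patSpacingMM)
  lab <- .resample3_nn(lab, truth@spacingMM, params@patSpacingMM, d_pat)
  img <- array(echo[lab + 1L], dim(lab))
  v <- params@noiseSD[["ultrasound"]]
  img <- .with_seed(seed, {
    if (v > 0)
      img <- img * array(rgamma(length(img), shape = 1 / v, scale = v),
                         dim(img))
    img
  })
  channelVolume(img, params@patSpacingMM, "ultrasound", side)
}
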