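# Synthetic labelled hyperspectral scenes.
#
# The generator emulates the statistical structure of airborne visible/NIR
# reflectance imagery of mixed agricultural-forest cover: smooth, strongly
# inter-band-correlated class spectra; vegetation classes with a red edge
# (NIR reflectance well above red); water with NIR below red; contiguous
# irregular class regions; class-dependent multiplicative spatial texture;
# additive sensor noise. It makes every downstream stage testable without
# any external download.

#' Specification of a synthetic scene
#'
#' @param height,width scene size in pixels (>= 32).
#' @param n_bands number of spectral bands (>= 8), evenly spaced over
#'   `wavelength_range`.
#' @param wavelength_range two wavelengths in nm; default `c(400, 1000)`,
#'   the visible-to-NIR window of typical airborne imaging spectrometers.
#' @param n_classes number of land-cover classes (>= 2); ids 1..n_classes,
#'   0 stays reserved for "unlabeled".
#' @param class_kinds character vector recycled over classes, drawn from
#'   `"vegetation"`, `"water"`, `"bare"`, `"built"`; controls the spectral
#'   shape (red edge, NIR decay, ...) of each endmember.
#' @param noise_sigma standard deviation of additive Gaussian noise, in
#'   reflectance units (default 0.01).
#' @param texture_amplitude amplitude of the per-class multiplicative texture
#'   field, in relative reflectance units (default 0.05). Multiplicative so
#'   the texture survives PCA and is visible to GLCM features.
#' @param blob_smoothness length scale, in pixels, of the class regions
#'   (default 32).
#' @param seed integer; one global seed fans out to per-stage child seeds so
#'   spectra, map and rendering can be regenerated independently.
#' @return An object of class `scene_spec`.
#' @examples
#' spec <- scene_spec(64, 64, n_bands = 16, n_classes = 3, seed = 1)
#' @export
scene_spec <- function(height = 256, width = 256, n_bands = 32,
                       wavelength_range = c(400, 1000), n_classes = 5,
                       class_kinds = c("vegetation", "water", "bare", "built"),
                       noise_sigma = 0.01, texture_amplitude = 0.05,
                       blob_smoothness = 32, seed = 1L) {
  if (!is_count(height, 32) || !is_count(width, 32))
    stopf("height and width must be integers >= 32")
  if (!is_count(n_bands, 8)) stopf("n_bands must be an integer >= 8")
  if (!is_count(n_classes, 2)) stopf("n_classes must be an integer >= 2")
  if (length(wavelength_range) != 2 || diff(wavelength_range) <= 0)
    stopf("wavelength_range must be increasing (nm)")
  class_kinds <- match.arg(class_kinds,
                           c("vegetation", "water", "bare", "built"),
                           several.ok = TRUE)
  kinds <- rep_len(class_kinds, n_classes)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_bands = as.integer(n_bands),
                 wavelength_range = wavelength_range,
                 n_classes = as.integer(n_classes), class_kinds = kinds,
                 noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 blob_smoothness = blob_smoothness, seed = as.integer(seed)),
            class = "scene_spec")
}

scene_wavelengths <- function(spec) {
  seq(spec$wavelength_range[1], spec$wavelength_range[2],
      length.out = spec$n_bands)
}

# Smooth random modulation over wavelength from a few Gaussian bumps.
gaussian_bumps <- function(wl, n_bumps, amp) {
  centers <- runif(n_bumps, min(wl), max(wl))
  widths <- runif(n_bumps, 60, 160)
  amps <- runif(n_bumps, -amp, amp)
  out <- numeric(length(wl))
  for (k in seq_len(n_bumps))
    out <- out + amps[k] * exp(-0.5 * ((wl - centers[k]) / widths[k])^2)
  out
}

# Archetypal reflectance curve per land-cover kind. Vegetation: chlorophyll
# absorption near 670 nm, green bump at 550 nm, red-edge sigmoid to a NIR
# plateau (scale 30 nm, wide enough that adjacent simulated bands stay
# strongly correlated at the default band spacing). Water: low, decaying
# toward NIR. Bare soil: gentle increasing ramp. Built: bright, nearly flat.
base_curve <- function(kind, wl) {
  switch(kind,
    vegetation = 0.10 + 0.06 * exp(-0.5 * ((wl - 550) / 40)^2) -
      0.04 * exp(-0.5 * ((wl - 670) / 45)^2) +
      0.45 / (1 + exp(-(wl - 715) / 30)),
    water = 0.18 * exp(-(wl - 400) / 260) + 0.01,
    bare = 0.18 + 0.25 * (wl - 400) / 600,
    built = 0.42 + 0.05 * sin((wl - 400) / 90))
}

spectral_angle <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a * a) * sum(b * b)))))
}

#' Generate class endmember spectra
#'
#' One smooth spectrum per class in `[0, 1]`, built from the kind's
#' archetypal curve plus a few seeded Gaussian bumps. Vegetation endmembers
#' satisfy NIR-region mean > red-region mean (red edge); water endmembers
#' the reverse. Classes sharing a kind are perturbed until every pair of
#' spectra is separated by at least `min_angle` radians of spectral angle.
#'
#' @param spec a [scene_spec()].
#' @param min_angle minimum pairwise spectral angle (radians, default 0.05)
#'   below which the generator refuses to emit near-duplicate classes.
#' @return List of endmembers, each `list(class_id, kind, spectrum)`.
#' @export
generate_endmembers <- function(spec, min_angle = 0.05) {
  wl <- scene_wavelengths(spec)
  red <- wl >= 620 & wl <= 700
  nir <- wl >= 760 & wl <= 950
  if (!any(red)) red <- which.min(abs(wl - 670))
  if (!any(nir)) nir <- which.min(abs(wl - 850))
  with_seed(child_seed(spec$seed, "endmembers"), {
    ems <- vector("list", spec$n_classes)
    for (ci in seq_len(spec$n_classes)) {
      kind <- spec$class_kinds[ci]
      ok <- FALSE
      for (attempt in 1:25) {
        s <- base_curve(kind, wl) + gaussian_bumps(wl, n_bumps = 4, amp = 0.06)
        s <- pmin(0.95, pmax(0.03, s))
        if (kind == "vegetation" && mean(s[nir]) <= mean(s[red]) + 0.05) next
        if (kind == "water" && mean(s[nir]) >= mean(s[red]) - 0.005) next
        seps <- vapply(ems[seq_len(ci - 1)],
                       function(e) spectral_angle(e$spectrum, s), numeric(1))
        if (ci == 1 || all(seps >= min_angle)) { ok <- TRUE; break }
      }
      if (!ok)
        stopf(paste0("could not place %d spectrally distinct classes at a ",
                     "separation floor of %.3f rad; lower `min_angle` or ",
                     "reduce n_classes"), spec$n_classes, min_angle)
      ems[[ci]] <- list(class_id = ci, kind = kind, spectrum = s)
    }
    ems
  })
}

# Smooth an H x W white-noise field with a separable Gaussian kernel of the
# given length scale, applied exactly via banded row/column weight matrices
# (renormalized at the borders, so no edge artefacts).
smooth_field <- function(H, W, length_scale) {
  z <- matrix(rnorm(H * W), H, W)
  kmat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / length_scale)^2)
    k / rowSums(k)
  }
  f <- kmat(H) %*% z %*% t(kmat(W))
  (f - mean(f)) / (sd(as.vector(f)) + 1e-12)
}

#' Generate a contiguous-blob class map
#'
#' Each class gets a seeded Gaussian-smoothed noise field with length scale
#' `blob_smoothness`; the per-pixel argmax over fields yields irregular,
#' interlocking contiguous regions. Every class id 1..n_classes is guaranteed
#' to appear (a small patch is stamped for any class the argmax missed);
#' 0 is never emitted.
#'
#' @param spec a [scene_spec()].
#' @param scheme optional [class_scheme()]; defaults to one named after the
#'   class kinds with kind-based first-level groups.
#' @return A [label_map()].
#' @export
generate_class_map <- function(spec, scheme = NULL) {
  if (is.null(scheme)) scheme <- default_scheme(spec)
  with_seed(child_seed(spec$seed, "classmap"), {
    fields <- lapply(seq_len(spec$n_classes), function(i)
      smooth_field(spec$height, spec$width, spec$blob_smoothness))
    lab <- matrix(1L, spec$height, spec$width)
    best <- fields[[1]]
    for (ci in seq_len(spec$n_classes)[-1]) {
      sel <- fields[[ci]] > best
      lab[sel] <- ci
      best[sel] <- fields[[ci]][sel]
    }
    missing <- setdiff(seq_len(spec$n_classes), unique(as.vector(lab)))
    for (ci in missing) {
      r0 <- sample.int(spec$height - 7L, 1L)
      c0 <- sample.int(spec$width - 7L, 1L)
      lab[r0:(r0 + 7L), c0:(c0 + 7L)] <- ci
    }
    label_map(lab, scheme)
  })
}

default_scheme <- function(spec) {
  kinds <- spec$class_kinds
  group_of <- c(vegetation = "Vegetation", water = "Waters",
                bare = "Bare areas", built = "Buildings")
  nm <- paste0(kinds, "_", seq_along(kinds))
  class_scheme(nm, groups = unname(group_of[kinds]))
}

#' Render a hyperspectral cube from endmembers and a class map
#'
#' Pixel spectrum = endmember(class) * (1 + class-dependent multiplicative
#' texture field of amplitude `texture_amplitude`) + iid Gaussian noise of
#' standard deviation `noise_sigma`, clipped to `[0, 1]`. Each class has its
#' own seeded texture field with a class-specific correlation length, so the
#' co-occurrence texture features carry class information.
#'
#' @param spec a [scene_spec()].
#' @param endmembers from [generate_endmembers()].
#' @param class_map a [label_map()] of matching size.
#' @return A [spectral_cube()].
#' @export
render_scene <- function(spec, endmembers, class_map) {
  lab <- class_map$labels
  if (!identical(dim(lab), c(spec$height, spec$width)))
    stopf("class map size does not match the scene spec")
  wl <- scene_wavelengths(spec)
  H <- spec$height; W <- spec$width; B <- spec$n_bands
  with_seed(child_seed(spec$seed, "render"), {
    tex <- matrix(0, H, W)
    if (spec$texture_amplitude > 0) {
      for (ci in seq_len(spec$n_classes)) {
        f <- smooth_field(H, W, length_scale = 1.5 + ci)
        sel <- lab == ci
        tex[sel] <- spec$texture_amplitude * f[sel]
      }
    }
    E <- do.call(rbind, lapply(endmembers, `[[`, "spectrum"))  # C x B
    base <- E[as.vector(lab), , drop = FALSE]                  # (H*W) x B
    modulated <- base * as.vector(1 + tex)
    if (spec$noise_sigma > 0)
      modulated <- modulated + rnorm(length(modulated), 0, spec$noise_sigma)
    arr <- array(pmin(1, pmax(0, modulated)), dim = c(H, W, B))
    spectral_cube(arr, wl)
  })
}

#' Generate a complete labelled synthetic scene
#'
#' Convenience wrapper: endmembers, class map and rendered cube in one call.
#'
#' @param spec a [scene_spec()].
#' @param scheme optional [class_scheme()].
#' @return `list(cube, labels, endmembers, spec)`.
#' @examples
#' sc <- simulate_scene(scene_spec(64, 64, n_bands = 16, n_classes = 3, seed = 2))
#' sc$cube
#' @export
simulate_scene <- function(spec, scheme = NULL) {
  ems <- generate_endmembers(spec)
  cmap <- generate_class_map(spec, scheme)
  cube <- render_scene(spec, ems, cmap)
  list(cube = cube, labels = cmap, endmembers = ems, spec = spec)
}
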