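# Fixed-axis pore-radius profiling of channel structures.
#
# Radius definition: at each axial sample the pore radius is the radius of
# the largest sphere centered ON the (fixed, straight) pore axis that
# overlaps no atomic van der Waals sphere, i.e.
#     r(z) = clamp( min_i ||p(z) - x_i|| - vdw_i , 0, scan_radius_cap ).
# This is a fixed-axis variant of the classic channel-profiling approach:
# deterministic, closed-form, and directly testable against ring geometries.
# Slab-based free-volume accounting (as in cavity-detection tools) can shift
# values slightly; the published 4.5/14 Angstrom structure numbers are
# benchmark targets for that reason, not unit tests.

# Bondi van der Waals radii (Angstrom)
.bondi_radii <- c(
  H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, As = 1.85,
  Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98, Xe = 2.16,
  Zn = 1.39, Cu = 1.40, Ni = 1.63, Na = 2.27, K = 2.75, Mg = 1.73,
  Li = 1.82, Ga = 1.87, In = 1.93, Sn = 2.17, Tl = 1.96, Pb = 2.02
)
.default_vdw <- 1.70
.water_resids <- c("HOH", "WAT", "TIP", "TIP3", "DOD", "SOL")

#' Construct an atom set
#'
#' @param x,y,z atomic coordinates (Angstrom).
#' @param element element symbols; used to assign Bondi van der Waals radii
#'   when `vdw` is not given (unknown elements get 1.70 Angstrom with a
#'   warning).
#' @param vdw optional explicit per-atom van der Waals radii (Angstrom).
#' @param chain,resno,resid optional record metadata.
#' @return A data frame of class `atom_set` with columns `element`, `x`,
#'   `y`, `z`, `vdw`, `chain`, `resno`, `resid`.
#' @export
atom_set <- function(x, y, z, element = "C", vdw = NULL, chain = "A",
                     resno = NA_integer_, resid = "UNK") {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n == 0L) stop("no atoms", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("non-finite coordinates", call. = FALSE)
  element <- rep_len(element, n)
  if (is.null(vdw)) {
    vdw <- unname(.bondi_radii[element])
    unknown <- is.na(vdw)
    if (any(unknown)) {
      warning("unknown element(s) assigned default vdW radius ",
              .default_vdw, " A: ",
              paste(unique(element[unknown]), collapse = ", "),
              call. = FALSE)
      vdw[unknown] <- .default_vdw
    }
  } else {
    vdw <- rep_len(vdw, n)
  }
  if (any(vdw <= 0)) stop("vdw radii must be positive", call. = FALSE)
  structure(data.frame(element = element, x = x, y = y, z = z, vdw = vdw,
                       chain = rep_len(chain, n),
                       resno = rep_len(resno, n),
                       resid = rep_len(resid, n),
                       stringsAsFactors = FALSE),
            class = c("atom_set", "data.frame"))
}

#' Load a channel structure from a PDB file
#'
#' Parses ATOM records (model 1) through `bio3d::read.pdb()`. Waters are
#' always excluded; other HETATM records are excluded unless
#' `include_hetero = TRUE`. Van der Waals radii are assigned per element
#' from the bundled Bondi table; unknown elements get 1.70 Angstrom with a
#' warning.
#'
#' @param path path to a PDB file.
#' @param include_hetero include non-water HETATM records (default `FALSE`).
#' @param chains optional character vector restricting to specific chains.
#' @param radii optional named numeric vector overriding the element radii
#'   table.
#' @return An [atom_set()].
#' @export
load_structure <- function(path, include_hetero = FALSE, chains = NULL,
                           radii = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("format error reading PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  keep <- !(a$resid %in% .water_resids)
  if (!include_hetero) keep <- keep & a$type == "ATOM"
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no atoms after filtering (waters/hetero excluded)", call. = FALSE)
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  # fall back to the first letter of the atom name when the element field
  # is blank (common in minimal hand-written files)
  elem[bad] <- substr(trimws(a$elety[bad]), 1L, 1L)
  elem <- trimws(elem)
  elem <- paste0(toupper(substr(elem, 1L, 1L)),
                 tolower(substr(elem, 2L, nchar(elem))))
  vdw <- NULL
  if (!is.null(radii)) {
    vdw <- unname(radii[elem])
    if (anyNA(vdw))
      stop("radii table lacks element(s): ",
           paste(unique(elem[is.na(vdw)]), collapse = ", "), call. = FALSE)
  }
  out <- atom_set(a$x, a$y, a$z, element = elem, vdw = vdw,
                  chain = a$chain, resno = a$resno, resid = a$resid)
  out$elety <- trimws(a$elety)
  out
}

#' Write an atom set to a PDB file
#'
#' Coordinates are written at standard PDB precision (1e-3 Angstrom).
#' Explicit per-atom radii are not representable in PDB; pass them back via
#' the `radii`/`vdw` arguments when reloading, or keep the in-memory
#' [atom_set()].
#'
#' @param atoms an [atom_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  stopifnot(inherits(atoms, "atom_set"))
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = ifelse(is.na(atoms$resno), 1L, atoms$resno),
                   resid = atoms$resid, chain = atoms$chain,
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$element, elesy = atoms$element)
  invisible(path)
}

#' Profiling parameters
#'
#' Axis lengths default to the published protocol: 120 Angstrom for a
#' hemichannel (`channel = "hc"`), 200 Angstrom for a gap junction channel
#' (`"gjc"`), with a 16 Angstrom scanning-radius cap and a 0.5 Angstrom
#' grid step.
#'
#' @param channel `"hc"` or `"gjc"`; sets the default `axis_length`.
#' @param axis_length length of the profiled axis (Angstrom); overrides the
#'   channel default.
#' @param grid_step axial sampling step (Angstrom, default 0.5).
#' @param scan_radius_cap maximum reported radius (Angstrom, default 16).
#' @param origin,direction axis origin and direction (3-vectors); the
#'   direction is normalized. Defaults to the deposited Z axis through the
#'   coordinate origin; see [default_axis()].
#' @return A `pore_params` list.
#' @export
pore_params <- function(channel = c("hc", "gjc"), axis_length = NULL,
                        grid_step = 0.5, scan_radius_cap = 16,
                        origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  channel <- match.arg(channel)
  if (is.null(axis_length))
    axis_length <- if (channel == "hc") 120 else 200
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  if (scan_radius_cap <= 0) stop("scan_radius_cap must be > 0", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("non-normalizable axis direction", call. = FALSE)
  structure(list(channel = channel, axis_length = axis_length,
                 grid_step = grid_step, scan_radius_cap = scan_radius_cap,
                 origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm),
            class = "pore_params")
}

#' Default pore axis of a structure
#'
#' The deposited Z axis through the alpha-carbon centroid (all atoms when no
#' alpha-carbons are present), with the axial extent centered on the atom
#' z-range.
#'
#' @param atoms an [atom_set()].
#' @return List with `origin` (3-vector) and `direction` (unit 3-vector).
#' @export
default_axis <- function(atoms) {
  stopifnot(inherits(atoms, "atom_set"), nrow(atoms) >= 1L)
  ca <- if ("elety" %in% names(atoms)) atoms[atoms$elety == "CA", ] else
    atoms[0L, ]
  ref <- if (nrow(ca) > 0L) ca else atoms
  origin <- c(mean(ref$x), mean(ref$y),
              (min(atoms$z) + max(atoms$z)) / 2)
  list(origin = origin, direction = c(0, 0, 1))
}

#' Compute a pore-radius profile
#'
#' Samples the axis every `grid_step` Angstrom over `axis_length` centered
#' on the origin. At each sample the radius is the distance from the axis
#' point to the nearest van der Waals sphere surface, clamped to
#' `[0, scan_radius_cap]`; with no atoms in reach the cap is reported.
#'
#' @param atoms an [atom_set()].
#' @param params a [pore_params()]; when `origin`/`direction` are left at
#'   their defaults and `use_default_axis = TRUE`, the axis from
#'   [default_axis()] is used.
#' @param use_default_axis replace the axis in `params` with
#'   [default_axis()] of `atoms` (default `FALSE`).
#' @return A data frame of class `pore_profile` with columns `z` (axial
#'   coordinate, Angstrom) and `radius` (Angstrom), and the parameters in
#'   `attr(, "params")`.
#' @examples
#' geom <- gen_pore_geometry(data.frame(z = 5, ring_radius = 10,
#'                                      n_atoms = 12, vdw = 1.7))
#' prof <- compute_profile(geom$atoms, pore_params("hc"))
#' prof$radius[prof$z == 5]  # 8.3
#' @export
compute_profile <- function(atoms, params = pore_params("hc"),
                            use_default_axis = FALSE) {
  stopifnot(inherits(atoms, "atom_set"), inherits(params, "pore_params"))
  if (use_default_axis) {
    ax <- default_axis(atoms)
    params$origin <- ax$origin
    params$direction <- ax$direction
  }
  u <- params$direction
  o <- params$origin
  half <- params$axis_length / 2
  offsets <- seq(-half, half, by = params$grid_step)
  # axial coordinate of each sample in the structure frame
  zc <- offsets + sum(o * u)
  pts <- cbind(o[1] + offsets * u[1],
               o[2] + offsets * u[2],
               o[3] + offsets * u[3])
  ax_ <- atoms$x; ay <- atoms$y; az <- atoms$z; av <- atoms$vdw
  radius <- vapply(seq_along(offsets), function(i) {
    d <- sqrt((ax_ - pts[i, 1])^2 + (ay - pts[i, 2])^2 +
                (az - pts[i, 3])^2) - av
    min(d)
  }, numeric(1))
  radius <- pmin(pmax(radius, 0), params$scan_radius_cap)
  structure(data.frame(z = zc, radius = radius),
            params = params, class = c("pore_profile", "data.frame"))
}

#' Locate profile extrema
#'
#' Global (or windowed) minimum and maximum radius with their axial
#' positions; ties resolve to the smallest z.
#'
#' @param profile a `pore_profile`.
#' @param z_window optional numeric length-2 range restricting the search.
#' @return List with `min` and `max`, each `c(z = , r = )`.
#' @export
locate_extrema <- function(profile, z_window = NULL) {
  stopifnot(inherits(profile, "pore_profile"), nrow(profile) >= 1L)
  df <- profile
  if (!is.null(z_window)) {
    stopifnot(length(z_window) == 2L)
    df <- df[df$z >= min(z_window) & df$z <= max(z_window), , drop = FALSE]
    if (nrow(df) == 0L) stop("empty z window", call. = FALSE)
  }
  i_min <- which(df$radius == min(df$radius))[1L]  # ties -> smallest z
  i_max <- which(df$radius == max(df$radius))[1L]
  list(min = c(z = df$z[i_min], r = df$radius[i_min]),
       max = c(z = df$z[i_max], r = df$radius[i_max]))
}
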