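#' Tabulated interaction potential
#'
#' A gridded potential for one interaction type. `grid` is strictly
#' increasing (nm for bond/nonbonded distances, degrees for angles and
#' dihedrals), `U` the energy in kJ/mol and `F = -dU/dx` on the same grid.
#' When `F` is omitted it is generated from the derivative of the natural
#' cubic spline through `U` — the same interpolant the MD engine evaluates,
#' so tabulated forces and engine forces agree by construction.
#'
#' @param kind one of `"bond"`, `"angle"`, `"dihedral"`, `"nonbonded"`.
#' @param grid strictly increasing abscissae.
#' @param U energies, kJ/mol.
#' @param F forces `-dU/dx`; computed from `U` when `NULL`.
#' @return an object of class `tabulated_potential`.
#' @export
tabulated_potential <- function(kind = c("bond", "angle", "dihedral", "nonbonded"),
                                grid, U, F = NULL) {
  kind <- match.arg(kind)
  grid <- as.numeric(grid); U <- as.numeric(U)
  if (length(grid) != length(U)) stop("grid and U lengths differ")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(!is.finite(U))) stop("U must be finite on the sampled range")
  if (is.null(F)) F <- -spline_deriv(grid, U, grid)
  structure(list(kind = kind, grid = grid, U = U, F = as.numeric(F)),
            class = "tabulated_potential")
}

#' @export
print.tabulated_potential <- function(x, ...) {
  cat(sprintf("tabulated_potential [%s]: %d points on [%.4g, %.4g], U in [%.4g, %.4g] kJ/mol\n",
              x$kind, length(x$grid), min(x$grid), max(x$grid), min(x$U), max(x$U)))
  invisible(x)
}

# derivative of the natural cubic spline through (x, y), evaluated at xout
spline_deriv <- function(x, y, xout) {
  if (length(x) < 4) {
    # too short for a spline: centred differences
    d <- diff(y) / diff(x)
    mid <- c(d[1], (head(d, -1) + tail(d, -1)) / 2, d[length(d)])
    return(approx(x, mid, xout, rule = 2)$y)
  }
  f <- stats::splinefun(x, y, method = "natural")
  f(xout, deriv = 1)
}

#' Evaluate a tabulated potential
#'
#' Natural cubic spline inside the sampled range, linear extrapolation of the
#' boundary slope outside it (matching the engine).
#'
#' @param potential a [tabulated_potential()].
#' @param x abscissae to evaluate at.
#' @param deriv 0 for energy, 1 for dU/dx.
#' @export
eval_potential <- function(potential, x, deriv = 0) {
  g <- potential$grid; U <- potential$U
  f <- stats::splinefun(g, U, method = "natural")
  lo <- x < g[1]; hi <- x > g[length(g)]
  out <- f(x, deriv = deriv)
  s1 <- f(g[1], deriv = 1); s2 <- f(g[length(g)], deriv = 1)
  if (deriv == 0) {
    out[lo] <- U[1] + s1 * (x[lo] - g[1])
    out[hi] <- U[length(g)] + s2 * (x[hi] - g[length(g)])
  } else {
    out[lo] <- s1; out[hi] <- s2
  }
  out
}

#' Write / read a tabulated potential
#'
#' Native dialect: `#`-prefixed metadata header then three whitespace-
#' separated columns `x U F`. The GROMACS-style dialect writes the seven
#' standard table columns (`x  f f'  g g'  h h'`) with the potential placed
#' in the `g/g'` pair for bonded kinds and `h/h'` for nonbonded dispersion;
#' reading that dialect back recovers the native table.
#'
#' @param potential a [tabulated_potential()].
#' @param path output file.
#' @param dialect `"native"` or `"gromacs"`.
#' @export
write_potential_table <- function(potential, path, dialect = c("native", "gromacs")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(potential, "tabulated_potential"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cgmelt potential table; kind=%s dialect=%s", potential$kind,
                     dialect), con)
  writeLines("# columns: x U[kJ/mol] F=-dU/dx", con)
  if (dialect == "native") {
    writeLines(sprintf("%.10e %.10e %.10e", potential$grid, potential$U,
                       potential$F), con)
  } else {
    z <- rep(0, length(potential$grid))
    writeLines(sprintf("%.10e %.10e %.10e %.10e %.10e %.10e %.10e",
                       potential$grid, z, z, z, z, potential$U, potential$F), con)
  }
  invisible(path)
}

#' @rdname write_potential_table
#' @param kind interaction kind to assign to the table read back.
#' @export
read_potential_table <- function(path, kind = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  km <- regmatches(meta[1], regexec("kind=(\\w+)", meta[1]))[[1]]
  if (is.null(kind)) kind <- if (length(km) == 2) km[2] else "nonbonded"
  dm <- regmatches(meta[1], regexec("dialect=(\\w+)", meta[1]))[[1]]
  dialect <- if (length(dm) == 2) dm[2] else "native"
  fields <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (dialect == "gromacs") {
    tabulated_potential(kind, fields[, 1], fields[, 6], fields[, 7])
  } else {
    tabulated_potential(kind, fields[, 1], fields[, 2], fields[, 3])
  }
}

#' A complete set of CG effective potentials
#'
#' Container for the four tabulated interactions of a bead-spring melt plus
#' the temperature they were derived at. Any component may be `NULL`.
#'
#' @param bond,angle,dihedral,nonbonded [tabulated_potential()] objects.
#' @param temperature temperature in K.
#' @export
potential_set <- function(bond = NULL, angle = NULL, dihedral = NULL,
                          nonbonded = NULL, temperature = 500) {
  for (p in list(bond, angle, dihedral, nonbonded))
    if (!is.null(p)) stopifnot(inherits(p, "tabulated_potential"))
  structure(list(bond = bond, angle = angle, dihedral = dihedral,
                 nonbonded = nonbonded, temperature = temperature),
            class = "potential_set")
}

#' @export
print.potential_set <- function(x, ...) {
  have <- names(Filter(Negate(is.null), x[c("bond", "angle", "dihedral", "nonbonded")]))
  cat(sprintf("potential_set at %g K: %s\n", x$temperature,
              paste(have, collapse = ", ")))
  invisible(x)
}

#' Write / read a potential set as a directory of tables
#'
#' @param potentials a [potential_set()].
#' @param dir directory (created if missing); one `<kind>.table` per component.
#' @export
write_potential_set <- function(potentials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in c("bond", "angle", "dihedral", "nonbonded")) {
    p <- potentials[[kind]]
    if (!is.null(p)) write_potential_table(p, file.path(dir, paste0(kind, ".table")))
  }
  writeLines(sprintf("temperature %g", potentials$temperature),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname write_potential_set
#' @export
read_potential_set <- function(dir) {
  comps <- lapply(setNames(nm = c("bond", "angle", "dihedral", "nonbonded")),
                  function(kind) {
                    p <- file.path(dir, paste0(kind, ".table"))
                    if (file.exists(p)) read_potential_table(p, kind) else NULL
                  })
  temperature <- 500
  mp <- file.path(dir, "meta.txt")
  if (file.exists(mp)) {
    ln <- readLines(mp)
    tv <- sub("^temperature +", "", ln[grep("^temperature ", ln)[1]])
    if (length(tv)) temperature <- as.numeric(tv)
  }
  potential_set(comps$bond, comps$angle, comps$dihedral, comps$nonbonded,
                temperature = temperature)
}

# engine-facing table list (NULL components preserved); the dihedral table is
# padded periodically (period 360 deg) so the spline slope is continuous
# across the -180/+180 seam
tables_for_engine <- function(potentials) {
  get <- function(k) {
    p <- potentials[[k]]
    if (is.null(p)) return(NULL)
    x <- p$grid; U <- p$U
    if (k == "dihedral" && length(x) > 8) {
      n <- length(x)
      tail_i <- (n - 4):(n - 1)
      head_i <- 2:5
      x <- c(x[tail_i] - 360, x, x[head_i] + 360)
      U <- c(U[tail_i], U, U[head_i])
      if (any(diff(x) <= 0)) { x <- p$grid; U <- p$U }  # non-spanning table
    }
    list(x = x, U = U)
  }
  list(bond = get("bond"), angle = get("angle"), dihedral = get("dihedral"),
       nonbonded = get("nonbonded"))
}
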