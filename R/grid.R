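#' Periodic Ramachandran grid
#'
#' A 2D grid over (phi, psi) on the periodic domain \[-180, 180) holding
#' overlap counts, energies (kJ/mol) or probabilities.  Bins are half-open
#' with centers at `-180 + step/2 + k * step` (for the default 2-degree
#' step: -179, -177, ..., 179); torsions are evaluated at bin centers.
#' Probability grids are normalized to sum to 1 over all bins.
#'
#' @param values numeric matrix, phi bins in rows, psi bins in columns.
#' @param phi_step,psi_step bin widths in degrees; must divide 360 and match
#'   the matrix dimensions.
#' @param kind one of `"overlap_count"`, `"energy_kJ_mol"`, `"probability"`.
#' @param meta named list of provenance fields (residue, lambda, chi_step,
#'   p_o, temperature, ...), carried through and written to file headers.
#' @return an object of class `rama_grid`.
#' @export
rama_grid <- function(values, phi_step, psi_step = phi_step,
                      kind = c("overlap_count", "energy_kJ_mol",
                               "probability"),
                      meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (360 %% phi_step != 0 || 360 %% psi_step != 0) {
    stop("grid steps must divide 360", call. = FALSE)
  }
  if (nrow(values) != 360 / phi_step || ncol(values) != 360 / psi_step) {
    stop("matrix dimensions do not match the grid steps", call. = FALSE)
  }
  if (kind == "probability") {
    if (any(values < 0)) stop("probabilities must be non-negative",
                              call. = FALSE)
    s <- sum(values)
    if (abs(s - 1) > 1e-8) values <- values / s
  }
  dimnames(values) <- list(format(bin_centers(phi_step)),
                           format(bin_centers(psi_step)))
  structure(values, phi_step = phi_step, psi_step = psi_step,
            kind = kind, meta = meta, class = c("rama_grid", "matrix"))
}

#' Bin centers of a periodic angle grid
#' @param step bin width in degrees.
#' @return numeric vector of bin centers in \[-180, 180).
#' @export
bin_centers <- function(step) -180 + step / 2 + step * seq_len(360 / step) - step

grid_kind <- function(g) attr(g, "kind")
grid_meta <- function(g) attr(g, "meta")

#' @export
print.rama_grid <- function(x, ...) {
  cat("<rama_grid> ", grid_kind(x), ", ",
      nrow(x), " x ", ncol(x), " bins (", attr(x, "phi_step"), " x ",
      attr(x, "psi_step"), " deg)\n", sep = "")
  m <- grid_meta(x)
  if (length(m)) {
    cat("  ", paste(names(m), unlist(lapply(m, format)), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  }
  cat("  range: [", format(min(x)), ", ", format(max(x)), "]\n", sep = "")
  invisible(x)
}

#' Long-format view of a Ramachandran grid
#'
#' @param x a [rama_grid()].
#' @param ... unused.
#' @return a tibble with columns `phi`, `psi`, `value`.
#' @method as_tibble rama_grid
#' @export
as_tibble.rama_grid <- function(x, ...) {
  phi <- bin_centers(attr(x, "phi_step"))
  psi <- bin_centers(attr(x, "psi_step"))
  phi_col <- rep(phi, times = length(psi))
  psi_col <- rep(psi, each = length(phi))
  tibble::tibble(phi = phi_col, psi = psi_col,
                 value = as.vector(unclass(x)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method tidy rama_grid
#' @export
tidy.rama_grid <- function(x, ...) as_tibble.rama_grid(x, ...)

#' Heatmap of a Ramachandran grid
#'
#' @param object a [rama_grid()].
#' @param trans optional transform for the fill scale, e.g. `"log10"` for
#'   probability grids.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rama_grid
#' @export
autoplot.rama_grid <- function(object, trans = "identity", ...) {
  df <- as_tibble.rama_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$psi,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = grid_kind(object)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a Ramachandran grid to a plain-text file
#'
#' Tabular format `phi psi value` with a `#`-prefixed header block carrying
#' the grid kind, steps and metadata, so files round-trip losslessly through
#' [read_rama_grid()] and are portable across languages.
#'
#' @param grid a [rama_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rama_grid <- function(grid, path) {
  meta <- grid_meta(grid)
  hdr <- c("# rama_grid",
           paste0("# kind: ", grid_kind(grid)),
           paste0("# phi_step: ", attr(grid, "phi_step")),
           paste0("# psi_step: ", attr(grid, "psi_step")),
           vapply(names(meta),
                  function(nm) paste0("# ", nm, ": ", format(meta[[nm]],
                                                             digits = 17)),
                  character(1L)))
  df <- as_tibble.rama_grid(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("phi psi value", con)
  writeLines(sprintf("%g %g %.17g", df$phi, df$psi, df$value), con)
  invisible(path)
}

#' Read a Ramachandran grid written by [write_rama_grid()]
#'
#' @param path file path.
#' @return a [rama_grid()].
#' @export
read_rama_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fields <- list()
  for (h in hdr[-1L]) {
    kv <- sub("^# *", "", h)
    key <- sub(":.*", "", kv)
    val <- sub("^[^:]*: *", "", kv)
    fields[[key]] <- val
  }
  phi_step <- as.numeric(fields$phi_step)
  psi_step <- as.numeric(fields$psi_step)
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  vals <- matrix(body$value, nrow = 360 / phi_step, ncol = 360 / psi_step)
  meta <- fields[setdiff(names(fields), c("kind", "phi_step", "psi_step"))]
  meta <- lapply(meta, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  rama_grid(vals, phi_step, psi_step, kind = fields$kind, meta = meta)
}
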