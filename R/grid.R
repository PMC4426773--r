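#' Build the two-region radial finite-volume grid
#'
#' Vertex-centred grid: nodes are uniformly spaced within each region, with
#' a node at the centre `r = 0`, a shared interface node exactly at `R_i`,
#' and a node at the outer edge `R_o = R_i (1 + hydrolysate_factor)`.
#' Control-volume faces sit midway between neighbouring nodes; the boundary
#' nodes own half-cells. Cell measures are cylindrical,
#' `V_k = (r_face_right^2 - r_face_left^2) / 2` (per unit length, per
#' radian), which reduces to `r_k * dr_k` for interior uniform nodes.
#'
#' @param geom A [material_geometry()].
#' @return An object of class `radial_grid`: a list with node radii `r`,
#'   interior face radii `r_face`, node spacings `dr_face = diff(r)`, cell
#'   widths `dr`, cylindrical cell measures `vol`, `region` tags
#'   (`"fibre"`/`"hydrolysate"`), `interface_index` and `R_o`.
#' @examples
#' g <- build_grid(material_geometry())
#' length(g$r)              # 350 nodes
#' g$r[g$interface_index]   # == R_i
#' @export
build_grid <- function(geom) {
  n_f <- geom$n_fibre; n_h <- geom$n_hydro
  R_i <- geom$R_i
  R_o <- R_i * (1 + geom$hydrolysate_factor)
  r_f <- seq(0, R_i, length.out = n_f)
  h_h <- (R_o - R_i) / n_h
  r_h <- R_i + h_h * seq_len(n_h)
  r <- c(r_f, r_h)
  n <- length(r)
  r_face <- (r[-1] + r[-n]) / 2          # interior faces, length n - 1
  faces <- c(0, r_face, R_o)             # all cell boundaries, length n + 1
  vol <- (faces[-1]^2 - faces[-(n + 1)]^2) / 2
  structure(list(r = r, r_face = r_face, dr_face = diff(r),
                 dr = diff(faces), vol = vol,
                 region = c(rep("fibre", n_f), rep("hydrolysate", n_h)),
                 interface_index = n_f, R_o = R_o),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  n <- length(x$r)
  cat(sprintf("<radial_grid> %d nodes (%d fibre + %d hydrolysate), R_i = %.3g m, R_o = %.3g m\n",
              n, x$interface_index, n - x$interface_index,
              x$r[x$interface_index], x$R_o))
  invisible(x)
}
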