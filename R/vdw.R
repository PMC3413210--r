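# van der Waals radius tables and contact classification thresholds.
#
# Primary dialect: Rowland & Taylor solid-state contact radii (H 1.10 A --
# the key difference from Bondi's 1.2 A), with Bondi values as fallback for
# elements absent from that compilation. Clash: center-to-center distance
# <= 0.8 x (r_a + r_b); severe clash: <= 0.7 x.
#
# Richardson dialect: the MolProbity-style system -- clash means van der
# Waals overlap >= 0.4 A, with H radii split by polarity (1.00 polar or
# aromatic, 1.17 otherwise).

.RT_RADII <- c(H = 1.10, C = 1.77, N = 1.64, O = 1.58, S = 1.81,
               F = 1.46, CL = 1.76, BR = 1.87, I = 2.03)

.BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                  SE = 1.90, B = 1.92, SI = 2.10, AS = 1.85,
                  ZN = 1.39, CU = 1.40, NI = 1.63, MG = 1.73, "NA" = 2.27,
                  K = 2.75, CA = 2.31, FE = 1.80, MN = 1.80, CD = 1.58,
                  HG = 1.55)

.RICHARDSON_RADII <- c(C = 1.70, N = 1.55, O = 1.40, S = 1.80, P = 1.80,
                       F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' van der Waals radius table
#'
#' Construct the radius table used by the clash engine, optionally merging a
#' user override table.
#'
#' @param mode `"primary"` (Rowland--Taylor radii; H = 1.10 Å) or
#'   `"richardson"` (overlap system; H = 1.00 Å polar/aromatic, 1.17 Å
#'   otherwise, O = 1.40 Å).
#' @param override optional named numeric vector or two-column data.frame
#'   (`element`, `radius`) replacing individual radii.
#' @return object of class `vdw_table`.
#' @export
vdw_table <- function(mode = c("primary", "richardson"), override = NULL) {
  mode <- match.arg(mode)
  radii <- if (mode == "primary") .RT_RADII else .RICHARDSON_RADII
  if (!is.null(override)) {
    if (is.data.frame(override)) {
      ov <- stats::setNames(as.numeric(override[[2]]), toupper(override[[1]]))
    } else {
      ov <- stats::setNames(as.numeric(override), toupper(names(override)))
    }
    stopifnot(all(ov > 0))
    radii[names(ov)] <- ov
  }
  structure(list(mode = mode, radii = radii,
                 h_polar_aromatic = 1.00, h_other = 1.17),
            class = "vdw_table")
}

#' Look up a van der Waals radius
#'
#' @param element element symbol (case-insensitive).
#' @param table a [vdw_table()].
#' @param polar_aromatic_h logical; in richardson mode, whether an H atom is
#'   bonded to N/O/S or to an aromatic ring atom (radius 1.00 Å) as opposed
#'   to any other H (1.17 Å). Ignored for non-H elements and in primary mode.
#' @return radius in Å.
#' @export
vdw_radius <- function(element, table = vdw_table(), polar_aromatic_h = FALSE) {
  el <- toupper(element)
  n <- max(length(el), length(polar_aromatic_h))
  el <- rep_len(el, n)
  pa <- rep_len(polar_aromatic_h, n)
  r <- numeric(n)
  ish <- el == "H" | el == "D"
  if (table$mode == "richardson") {
    r[ish] <- ifelse(pa[ish], table$h_polar_aromatic, table$h_other)
  } else {
    r[ish] <- table$radii[["H"]]
  }
  if (any(!ish)) {
    rr <- table$radii[el[!ish]]
    if (anyNA(rr)) {
      missing_el <- unique(el[!ish][is.na(rr)])
      bondi <- .BONDI_RADII[missing_el]
      if (anyNA(bondi)) {
        stop("no van der Waals radius known for element(s): ",
             paste(missing_el[is.na(bondi)], collapse = ", "))
      }
      warning("element(s) ", paste(missing_el, collapse = ", "),
              " not in ", table$mode, " table; using Bondi fallback")
      names(rr) <- el[!ish]
      rr[is.na(rr)] <- bondi[el[!ish][is.na(rr)]]
    }
    r[!ish] <- rr
  }
  unname(r)
}

#' @export
print.vdw_table <- function(x, ...) {
  cat("<vdw_table> mode:", x$mode, "\n")
  print(round(x$radii, 2))
  if (x$mode == "richardson")
    cat("H: polar/aromatic", x$h_polar_aromatic, "/ other", x$h_other, "\n")
  invisible(x)
}
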