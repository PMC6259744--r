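# Descriptor stage: charge differences across the ester C(-O2)(=O1) moiety
# and bond polarities (charge difference times bond length), assembled per
# theory/solvation level into the full descriptor table.

#' Charge difference across a bond
#'
#' `q_a - q_b`, with `q_b` the oxygen's signed (usually negative) Mulliken
#' charge, so typical carbonyl/ester values are positive.
#'
#' @param q_a,q_b atomic partial charges (e); vectorised.
#' @return `q_a - q_b` (e).
#' @export
#' @examples
#' charge_difference(0.2991, -0.2580)  # 0.5571
charge_difference <- function(q_a, q_b) {
  if (!is.numeric(q_a) || !is.numeric(q_b) || anyNA(q_a) || anyNA(q_b) ||
      any(!is.finite(q_a)) || any(!is.finite(q_b)))
    ek_stop("charges must be finite numerics", "esterkin_validation_error")
  q_a - q_b
}

#' Bond polarity descriptor
#'
#' The product of the partial-charge difference across a bond and the bond
#' length. With the charge difference in elementary charges and the length
#' in Å the descriptor is in e·Å; it scales linearly in the charge
#' difference and carries its sign.
#'
#' @param delta_q charge difference across the bond (e); vectorised.
#' @param d bond length (Å, > 0).
#' @return `delta_q * d` (e·Å).
#' @export
#' @examples
#' bond_polarity(0.5571, 1.381)  # 0.7694 at 4 decimals
bond_polarity <- function(delta_q, d) {
  if (!is.numeric(delta_q) || anyNA(delta_q))
    ek_stop("'delta_q' must be numeric", "esterkin_validation_error")
  if (!is.numeric(d) || anyNA(d) || any(d <= 0))
    ek_stop("bond length 'd' must be positive", "esterkin_geometry_error")
  delta_q * d
}

#' Assemble the full descriptor table
#'
#' Builds, per theory/solvation level and ester, the charge differences
#' `C-O2` and `C-O1` and bond polarities `P_C-O2` and `P_C=O1` from the
#' supplied Mulliken charges, always pairing them with the ester's
#' AM1-optimised bond lengths (the convention under which the published
#' derived values reproduce). Raw charges, bond lengths and any passthrough
#' descriptors (steric hindrance, cLogP) are carried along unchanged.
#'
#' @param charges `data.frame` with columns `ester`, `level`, `q_C`,
#'   `q_O1`, `q_O2`; levels must belong to [table1_levels()] and every
#'   requested ester/level pair must be present.
#' @param geometry `data.frame` with columns `ester`, `d_C_O2`, `d_C_O1`
#'   (Å, AM1); its ester order fixes the table's column order.
#' @param steric,clogp optional per-ester passthrough descriptors, in
#'   `geometry`'s ester order.
#' @param levels levels to include, default all present in `charges`.
#' @param annotations optional annotation table (see [load_table1()]);
#'   rows derived from `typo`-flagged charge cells trigger a warning and
#'   are marked in the `flagged` column.
#' @return A `data.frame` of class `descriptor_table`: columns `level`,
#'   `quantity`, one column per ester, and `flagged`; one row per
#'   descriptor. Global rows (`level == "global"`) hold bond lengths and
#'   passthrough descriptors.
#' @seealso [screen_descriptors()]
#' @export
#' @examples
#' t1 <- load_table1()
#' d <- build_descriptor_table(t1$charges, t1$geometry,
#'                             steric = t1$esters$steric_hindrance,
#'                             clogp = t1$esters$cLogP,
#'                             annotations = t1$annotations)
#' d[d$quantity == "P_C-O2", ]
build_descriptor_table <- function(charges, geometry, steric = NULL,
                                   clogp = NULL, levels = NULL,
                                   annotations = NULL) {
  need <- c("ester", "level", "q_C", "q_O1", "q_O2")
  if (!is.data.frame(charges) || !all(need %in% names(charges)))
    ek_stop(paste("'charges' needs columns", paste(need, collapse = ", ")),
            "esterkin_schema_error")
  if (!is.data.frame(geometry) ||
      !all(c("ester", "d_C_O2", "d_C_O1") %in% names(geometry)))
    ek_stop("'geometry' needs columns ester, d_C_O2, d_C_O1",
            "esterkin_schema_error")
  if (any(geometry$d_C_O2 <= 1 | geometry$d_C_O2 >= 2 |
          geometry$d_C_O1 <= 1 | geometry$d_C_O1 >= 2))
    ek_stop("bond lengths outside the sanity range (1, 2) Angstrom",
            "esterkin_geometry_error")
  esters <- as.character(geometry$ester)
  if (is.null(levels)) levels <- unique(charges$level)
  bad <- setdiff(levels, table1_levels())
  if (length(bad))
    ek_stop(paste0("unknown theory/solvation level(s): ",
                   paste(bad, collapse = "; "),
                   " — must be one of table1_levels()"),
            "esterkin_validation_error")
  grid <- expand.grid(ester = esters, level = levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(e, l) paste(e, l, sep = "\r")
  have <- key(charges$ester, charges$level)
  miss <- !(key(grid$ester, grid$level) %in% have)
  if (any(miss))
    ek_stop(paste0("missing charge set(s) for: ",
                   paste(sprintf("%s @ %s", grid$ester[miss],
                                 grid$level[miss]), collapse = "; ")),
            "esterkin_incomplete_error")

  if (!is.null(annotations)) {
    flagged_in <- vapply(seq_len(nrow(charges)), function(i) {
      q <- c(q_C = "C", q_O1 = "O1", q_O2 = "O2")
      any(vapply(names(q), function(col)
        annotation_matches(annotations, charges$level[i], q[[col]],
                           charges$ester[i]), logical(1)))
    }, logical(1))
    if (any(flagged_in))
      ek_warn(paste0("derived descriptors use typo-flagged charge cells: ",
                     paste(unique(sprintf("%s @ %s", charges$ester[flagged_in],
                                          charges$level[flagged_in])),
                           collapse = "; ")),
              "esterkin_flagged_cell_warning")
  }

  row_of <- function(level, quantity, values)
    cbind(data.frame(level = level, quantity = quantity,
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(as.list(values)), esters))
  rows <- list(
    row_of("global", "d_C_O2", geometry$d_C_O2),
    row_of("global", "d_C_O1", geometry$d_C_O1)
  )
  for (lv in levels) {
    ch <- charges[charges$level == lv, ]
    ch <- ch[match(esters, ch$ester), ]
    dq2 <- charge_difference(ch$q_C, ch$q_O2)
    dq1 <- charge_difference(ch$q_C, ch$q_O1)
    rows <- c(rows, list(
      row_of(lv, "C", ch$q_C),
      row_of(lv, "O2", ch$q_O2),
      row_of(lv, "O1", ch$q_O1),
      row_of(lv, "C-O2", dq2),
      row_of(lv, "C-O1", dq1),
      # AM1 geometry for every level's polarity, by construction
      row_of(lv, "P_C-O2", bond_polarity(dq2, geometry$d_C_O2)),
      row_of(lv, "P_C=O1", bond_polarity(dq1, geometry$d_C_O1))
    ))
  }
  if (!is.null(steric)) rows <- c(rows, list(row_of("global", "steric_hindrance", steric)))
  if (!is.null(clogp)) rows <- c(rows, list(row_of("global", "cLogP", clogp)))
  out <- do.call(rbind, rows)
  out$flagged <- if (is.null(annotations)) FALSE else
    vapply(seq_len(nrow(out)), function(i)
      annotation_matches(annotations, out$level[i], out$quantity[i]),
      logical(1))
  class(out) <- c("descriptor_table", "data.frame")
  attr(out, "esters") <- esters
  attr(out, "levels") <- levels
  out
}

#' @export
print.descriptor_table <- function(x, digits = 4, ...) {
  cat(sprintf("<descriptor_table> %d descriptors x %d esters (%d flagged rows)\n",
              nrow(x), length(attr(x, "esters")), sum(x$flagged)))
  shown <- as.data.frame(x)
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = digits)
  print(shown, row.names = FALSE)
  invisible(x)
}
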