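# Numeric encoding of the subject-level predictor grid for the
# multivariate-normal working model: continuous as-is, binary as {0,1},
# nominal variables as a dummy block (reference level dropped), with the
# decode step mapping an imputed dummy block back to the nearest level
# vertex. The grid has one row per subject; predictors are constant within
# subject in this design, and `time_weeks` (the visit schedule) is excluded
# from the grid because a masked week is recovered deterministically from
# the subject's visit index.

build_encoding <- function(table) {
  types <- attr(table, "predictor_types")
  vars <- setdiff(names(types), "time_weeks")
  enc <- list()
  for (nm in vars) {
    tp <- types[[nm]]
    if (tp == "categorical") {
      lv <- sort(unique(stats::na.omit(as.character(table[[nm]]))))
      enc[[nm]] <- list(type = tp, levels = lv,
                        cols = if (length(lv) > 1)
                          paste0(nm, "..", lv[-1]) else nm)
    } else {
      enc[[nm]] <- list(type = tp, cols = nm)
    }
  }
  enc
}

# Subject-level grid (one row per subject) from a long table.
subject_grid <- function(table) {
  df <- as.data.frame(table)
  ids <- unique(df$subject_id)
  first <- match(ids, df$subject_id)
  grid <- df[first, , drop = FALSE]
  rownames(grid) <- ids
  grid
}

encode_grid <- function(grid, encoding) {
  cols <- unlist(lapply(encoding, `[[`, "cols"), use.names = FALSE)
  X <- matrix(NA_real_, nrow(grid), length(cols),
              dimnames = list(rownames(grid), cols))
  for (nm in names(encoding)) {
    e <- encoding[[nm]]
    v <- grid[[nm]]
    if (e$type == "categorical" && length(e$levels) > 1) {
      for (lv in e$levels[-1])
        X[, paste0(nm, "..", lv)] <- ifelse(is.na(v), NA_real_,
                                            as.numeric(v == lv))
    } else {
      X[, e$cols] <- as.numeric(v)
    }
  }
  X
}

# Map an encoded (possibly continuous-valued) grid back to predictor
# values: dummy blocks to the nearest level vertex, binaries thresholded,
# bounded continuous variables clipped.
decode_grid <- function(X, encoding, specs = NULL) {
  out <- list()
  for (nm in names(encoding)) {
    e <- encoding[[nm]]
    if (e$type == "categorical" && length(e$levels) > 1) {
      D <- X[, e$cols, drop = FALSE]
      verts <- rbind(0, diag(length(e$levels) - 1))  # rows = levels
      pick <- apply(D, 1, function(row) {
        which.min(colSums((t(verts) - row)^2))
      })
      out[[nm]] <- e$levels[pick]
    } else if (e$type == "binary") {
      out[[nm]] <- as.integer(X[, e$cols] >= 0.5)
    } else {
      v <- X[, e$cols]
      sp <- specs[[nm]]
      if (!is.null(sp$lower)) v <- pmax(v, sp$lower)
      if (!is.null(sp$upper)) v <- pmin(v, sp$upper)
      if (isTRUE(sp$integer)) v <- round(v)
      out[[nm]] <- v
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
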