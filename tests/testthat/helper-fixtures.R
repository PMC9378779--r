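# Shared fixtures (memoised per test run) and independent oracles.

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

# the "default synthetic section": control preset, ~500 planted cells
default_section <- function() {
  get_fixture("default_section", function() {
    lay <- make_compartment_layout(2000, 2000, seed = 101)
    simulate_section(lay, default_presets()$control, seed = 102,
                     patient_id = "ctrl_fixture")
  })
}

default_cells <- function() {
  get_fixture("default_cells", function() {
    sec <- default_section()
    suppressMessages(
      quantify_section(sec$image, sec$layout, study_config(), "ctrl_fixture"))
  })
}

# a full 25-patient study (images streamed, not retained)
full_study <- function() {
  get_fixture("full_study", function() {
    suppressMessages(run_study(seed = 301))
  })
}

# a QC-filtered, normalised scRNA-seq dataset with planted truth
scrna_fixture <- function() {
  get_fixture("scrna_fixture", function() {
    sim <- simulate_counts(seed = 5)
    flt <- suppressWarnings(qc_filter(sim$counts))
    expr <- normalize_log(flt$counts)
    mast <- select_mast_cells(expr)
    ids <- mast$cell_id[mast$is_mast]
    list(sim = sim, expr = expr, mast = mast, ids = ids,
         cls = split_cpa3(expr, ids))
  })
}

# greedy bipartite nearest-centroid matching between measured and truth cells
match_to_truth <- function(cells, truth, max_dist_um = 5) {
  if (nrow(cells) == 0 || nrow(truth) == 0) {
    return(list(truth_idx = integer(0), cell_idx = integer(0)))
  }
  d2 <- outer(cells$x_um, truth$x_um, "-")^2 + outer(cells$y_um, truth$y_um, "-")^2
  cand <- which(d2 <= max_dist_um^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list(truth_idx = integer(0), cell_idx = integer(0)))
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_c <- logical(nrow(cells)); used_t <- logical(nrow(truth))
  ti <- integer(0); ci <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_c[i] && !used_t[j]) {
      used_c[i] <- TRUE; used_t[j] <- TRUE
      ci <- c(ci, i); ti <- c(ti, j)
    }
  }
  list(truth_idx = ti, cell_idx = ci)
}

# brute-force 8-connected labelling by BFS flood fill (oracle for
# label_components); returns an integer label matrix
flood_fill_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# do two labelings induce the same partition of foreground pixels?
# (canonicalise both by first-occurrence renumbering in scan order)
canonical_labels <- function(lab) {
  f <- as.integer(lab[lab > 0])
  if (!length(f)) return(matrix(0L, nrow(lab), ncol(lab)))
  u <- unique(f)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[f]
  matrix(as.integer(lab), nrow(lab), ncol(lab))
}
same_partition <- function(a, b) {
  identical(canonical_labels(a), canonical_labels(b))
}

# tiny single-compartment annotation helpers
square_annotation <- function(side_um = 500, label = "alveolar_parenchyma") {
  compartment_annotation(label,
                         list(rect_poly(0, 0, side_um, side_um)),
                         section_id = "toy")
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# toy multiplex image with constant channels
toy_image <- function(h = 20, w = 20, nuclei = 100, mrna = 0, protein = 0,
                      tryptase = 0, pixel_size_um = 1) {
  multiplex_image(list(nuclei = matrix(nuclei, h, w),
                       mrna = matrix(mrna, h, w),
                       protein = matrix(protein, h, w),
                       tryptase = matrix(tryptase, h, w)),
                  pixel_size_um = pixel_size_um, source_id = "toy")
}

# brute-force per-cell QC predicate (oracle for qc_filter)
brute_force_qc <- function(cm, config) {
  counts <- as.matrix(cm$counts)
  keep <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    v <- counts[, j]
    ng <- sum(v > 0)
    tot <- sum(v)
    mf <- if (tot > 0) sum(v[cm$mito]) / tot else 0
    keep[j] <- ng >= config$gene_min && ng <= config$gene_max &&
      tot >= config$umi_min && tot <= config$umi_max &&
      mf >= 0 && mf <= config$mito_max_frac
  }
  keep
}
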