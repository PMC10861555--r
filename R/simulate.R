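#' @include AllClasses.R ranges.R io.R
#' @importFrom stats rnorm runif rbinom
NULL

#' Simulate a paired multiome with a planted regulatory network
#'
#' Generates cell-by-gene expression and cell-by-peak accessibility matrices
#' from a known ground-truth network so the whole pipeline can be validated
#' without external data. The generative chain: (1) each cell takes one of
#' two states (fraction \code{state_fraction} in state B) and a lognormal
#' size factor; (2) TF expression is a state-dependent mean plus Gaussian
#' noise, clipped at zero; (3) each target gene's latent drive is the
#' planted linear combination of its true TFs' expression; true-CRE
#' accessibility is a noisy linear readout of that same (standardized)
#' drive, with weights arranged so the gene's expression is simultaneously
#' an exact linear model in its true CRE accessibilities (planted CRE
#' effects) and in its true TFs' expression (planted TF effects); decoy
#' peaks are independent noise; (4) gene expression adds Gaussian noise of
#' sd \code{noise_sd}; (5) each true TF's motif is placed in at least one
#' true CRE of its target (plus the promoter half the time), with sparse
#' random background placements; (6) DEG directions follow the planted
#' state shifts, and a 2-D embedding separates the states. All draws are
#' deterministic given \code{seed}.
#'
#' Genes alternate strand along one chromosome, spaced 1.2 Mb so candidate
#' windows do not share peaks. Each gene gets one promoter peak (an
#' activating true CRE with effect in the upper half of
#' \code{effect_range}), \code{true_cres_per_gene - 1} distal true CREs at
#' log-uniform distances in [2 kb, 450 kb], and decoys at uniform distances
#' within the window; a fraction \code{frac_repressive} of distal true CREs
#' are repressive.
#'
#' @param n_cells,n_genes,n_tfs problem dimensions (\code{n_tfs <=
#'   n_genes})
#' @param peaks_per_gene candidate peaks per gene
#' @param true_cres_per_gene true CREs per gene (incl. the promoter peak)
#' @param true_tfs_per_gene true regulators per gene
#' @param effect_range |effect| range for both CRE and TF effects
#' @param noise_sd Gaussian sd of gene expression noise
#' @param state_fraction fraction of cells in state B (0 = single state)
#' @param seed RNG seed
#' @param frac_repressive fraction of distal true CREs with negative effect
#' @param acc_noise_sd sd of the CRE-specific accessibility component
#' @param tf_noise_sd sd of TF expression noise
#' @param size_factor_sd lognormal sd of per-cell size factors
#' @param motif_bg_rate background motif placement probability
#' @return list: \code{expr} (cells x genes+TFs \linkS4class{OmicsMatrix}),
#'   \code{acc}, \code{peaks}, \code{genes}, \code{motifs}, \code{hits},
#'   \code{deg}, \code{embedding}, \code{truth} (planted links, placements,
#'   states, per-gene state effects)
#' @export
simulateMultiome <- function(n_cells = 2000, n_genes = 50, n_tfs = 30,
                             peaks_per_gene = 50, true_cres_per_gene = 5,
                             true_tfs_per_gene = 3, effect_range = c(0.5, 2),
                             noise_sd = 0.5, state_fraction = 0.5, seed = 7,
                             frac_repressive = 0.3, acc_noise_sd = 0.5,
                             tf_noise_sd = 0.6, size_factor_sd = 0.1,
                             motif_bg_rate = 0.02) {
  if (true_cres_per_gene > peaks_per_gene)
    stop("true_cres_per_gene must be <= peaks_per_gene")
  if (n_tfs > n_genes) stop("n_tfs must be <= n_genes")
  if (true_tfs_per_gene > n_tfs) stop("true_tfs_per_gene must be <= n_tfs")

  withr::with_seed(as.integer(seed), {
    cells <- sprintf("cell%05d", seq_len(n_cells))
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    tf_ids <- sprintf("TF%02d", seq_len(n_tfs))

    ## --- cell states and size factors ---
    is_b <- runif(n_cells) < state_fraction
    states <- stats::setNames(ifelse(is_b, "stateB", "stateA"), cells)
    sf <- exp(rnorm(n_cells, 0, size_factor_sd))

    ## --- TF expression: state-dependent mean + noise, clipped at 0 ---
    tf_base <- runif(n_tfs, 2.5, 4)
    tf_shift <- if (state_fraction > 0 && state_fraction < 1) {
      sample(c(-1, 1), n_tfs, replace = TRUE) * runif(n_tfs, 0.5, 1.2)
    } else rep(0, n_tfs)
    tf_expr <- sapply(seq_len(n_tfs), function(t) {
      pmax(0, tf_base[t] + tf_shift[t] * is_b + rnorm(n_cells, 0, tf_noise_sd))
    })
    colnames(tf_expr) <- tf_ids

    ## --- genomic layout ---
    spacing <- 1200000
    tss <- 600000 + (seq_len(n_genes) - 1) * spacing
    strands <- rep(c("+", "-"), length.out = n_genes)
    body_start <- ifelse(strands == "+", tss, tss - 19999)
    body_end <- ifelse(strands == "+", tss + 20000, tss + 1)
    genes <- GeneAnnotation(gene_ids, "chr1", strands, body_start, body_end)

    n_distal_true <- true_cres_per_gene - 1
    n_decoy <- peaks_per_gene - true_cres_per_gene
    peak_rows <- list(); true_cre <- list(); tf_links <- list()
    expr_genes <- matrix(0, n_cells, n_genes, dimnames = list(cells, gene_ids))
    acc_cols <- list()
    state_eff <- stats::setNames(numeric(n_genes), gene_ids)
    placements <- list()

    for (g in seq_len(n_genes)) {
      up <- if (strands[g] == "+") -1 else 1   # genomic direction of "upstream"
      ## promoter peak inside the -2000..0 promoter
      prom_start <- if (strands[g] == "+") tss[g] - 1400 else tss[g] + 801
      starts <- prom_start
      kinds <- "promoter"
      ## distal true CREs, log-uniform 2 kb - 450 kb
      d <- exp(runif(n_distal_true, log(2000), log(450000)))
      side <- sample(c(-1, 1), n_distal_true, replace = TRUE)
      starts <- c(starts, round(tss[g] + side * d - 250))
      kinds <- c(kinds, rep("true", n_distal_true))
      ## decoys, uniform within the window
      dd <- runif(n_decoy, 2000, 480000)
      sided <- sample(c(-1, 1), n_decoy, replace = TRUE)
      starts <- c(starts, round(tss[g] + sided * dd - 250))
      kinds <- c(kinds, rep("decoy", n_decoy))
      while (anyDuplicated(starts))
        starts[duplicated(starts)] <- starts[duplicated(starts)] + 531
      widths <- c(600, rep(500, n_distal_true + n_decoy))
      pid <- sprintf("chr1:%d-%d", as.integer(starts),
                     as.integer(starts + widths))
      peak_rows[[g]] <- data.frame(start = starts, end = starts + widths,
                                   peak_id = pid, kind = kinds,
                                   gene = gene_ids[g])

      ## planted TF effects and latent drive
      t_idx <- sample(n_tfs, true_tfs_per_gene)
      theta <- sample(c(-1, 1), true_tfs_per_gene, replace = TRUE) *
        runif(true_tfs_per_gene, effect_range[1], effect_range[2])
      D <- as.numeric(tf_expr[, t_idx, drop = FALSE] %*% theta)
      sD <- stats::sd(D)
      if (sD == 0) sD <- 1
      L <- (D - mean(D)) / sD
      tf_links[[g]] <- data.frame(tf_id = tf_ids[t_idx], gene_id = gene_ids[g],
                                  effect = theta)

      ## planted CRE effects: promoter activating and strong, distal mixed
      beta <- c(runif(1, mean(effect_range), effect_range[2]),
                sample(c(-1, 1), n_distal_true, replace = TRUE,
                       prob = c(frac_repressive, 1 - frac_repressive)) *
                  runif(n_distal_true, effect_range[1], effect_range[2]))
      q <- runif(true_cres_per_gene, 0.5, 1.5)
      q <- q / sum(q)
      mu <- c(runif(1, 3, 4.5), runif(n_distal_true, 2.5, 4))
      acc_true <- sapply(seq_len(true_cres_per_gene), function(k) {
        pmax(0, mu[k] + (q[k] / beta[k]) * L +
               rnorm(n_cells, 0, acc_noise_sd))
      })
      true_ids <- pid[kinds != "decoy"]
      colnames(acc_true) <- true_ids
      true_cre[[g]] <- data.frame(gene_id = gene_ids[g], peak_id = true_ids,
                                  effect = beta)

      ## decoys: independent noise, a third with their own state shift
      acc_dec <- sapply(seq_len(n_decoy), function(k) {
        shift <- if (runif(1) < 1 / 3 && state_fraction > 0)
          sample(c(-1, 1), 1) * runif(1, 0.3, 0.8) else 0
        pmax(0, runif(1, 0.5, 2.5) + shift * is_b + rnorm(n_cells, 0, 0.7))
      })
      colnames(acc_dec) <- pid[kinds == "decoy"]
      acc_cols[[g]] <- cbind(acc_true, acc_dec)

      drive <- as.numeric(acc_true %*% beta)
      base_g <- max(0.5, 0.5 - min(drive))
      expr_genes[, g] <- base_g + drive + rnorm(n_cells, 0, noise_sd)
      state_eff[g] <- if (any(is_b) && any(!is_b)) {
        mean(expr_genes[is_b, g]) - mean(expr_genes[!is_b, g])
      } else 0

      ## guaranteed motif placements for the true TFs
      n_in <- pmin(length(true_ids) - 1L, sample(1:2, true_tfs_per_gene,
                                                 replace = TRUE))
      pl <- lapply(seq_len(true_tfs_per_gene), function(j) {
        in_cres <- if (n_in[j] > 0) sample(true_ids[-1], n_in[j]) else character()
        if (n_in[j] == 0L || runif(1) < 0.5) in_cres <- c(in_cres, true_ids[1])
        data.frame(peak_id = in_cres, motif_id = paste0("M_", tf_ids[t_idx[j]]))
      })
      placements[[g]] <- do.call(rbind, pl)
    }

    peak_df <- do.call(rbind, peak_rows)
    peaks <- PeakSet("chr1", peak_df$start, peak_df$end,
                     peak_id = peak_df$peak_id)
    acc_mat <- do.call(cbind, acc_cols)
    rownames(acc_mat) <- cells

    ## size factors scale both modalities of a cell
    expr_all <- cbind(expr_genes, tf_expr) * sf
    acc_mat <- acc_mat * sf

    ## motifs: sharp random-consensus PFMs, one per TF
    motif_ids <- paste0("M_", tf_ids)
    pfms <- lapply(motif_ids, function(m) {
      cons <- sample(4, 8, replace = TRUE)
      pfm <- matrix(5, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
      pfm[cbind(cons, 1:8)] <- 85
      pfm
    })
    names(pfms) <- motif_ids
    motifs <- new("MotifSet", pfms = pfms,
                  tfNames = stats::setNames(tf_ids, motif_ids),
                  background = stats::setNames(
                    rep(list(stats::setNames(rep(0.25, 4),
                                             c("A", "C", "G", "T"))),
                        n_tfs), motif_ids))

    ## hit matrix: guaranteed placements plus sparse background
    pl <- unique(do.call(rbind, placements))
    hits_m <- Matrix::sparseMatrix(
      i = match(pl$peak_id, peak_df$peak_id),
      j = match(pl$motif_id, motif_ids),
      dims = c(nrow(peak_df), n_tfs),
      dimnames = list(peak_df$peak_id, motif_ids), x = 1)
    draw <- which(runif(nrow(peak_df) * n_tfs) < motif_bg_rate) - 1L
    bg <- Matrix::sparseMatrix(
      i = draw %% nrow(peak_df) + 1L, j = draw %/% nrow(peak_df) + 1L,
      dims = c(nrow(peak_df), n_tfs), dimnames = dimnames(hits_m), x = 1)
    hits <- peakMotifHits(((hits_m + bg) > 0) * 1)

    deg <- if (any(is_b) && any(!is_b)) {
      degTable(gene_ids, ifelse(state_eff[gene_ids] >= 0, -1L, 1L))
    } else degTable(character(), integer())

    embedding <- cbind(dim1 = ifelse(is_b, 6, 0) + rnorm(n_cells, 0, 1),
                       dim2 = rnorm(n_cells, 0, 1))
    rownames(embedding) <- cells

    gc <- stats::setNames(runif(nrow(peak_df), 0.3, 0.7), peak_df$peak_id)

    list(expr = OmicsMatrix(expr_all, "rna", units = "normalized"),
         acc = OmicsMatrix(acc_mat, "atac", units = "normalized"),
         peaks = peaks, genes = genes, motifs = motifs, hits = hits,
         deg = deg, embedding = embedding, gc = gc,
         truth = list(true_cre_links = do.call(rbind, true_cre),
                      true_tf_links = do.call(rbind, tf_links),
                      motif_placements = pl, cell_states = states,
                      state_effects = state_eff, noise_sd = noise_sd,
                      seed = seed))
  })
}

#' Recovery metrics against a planted truth
#'
#' Confusion-set arithmetic over (gene, element) pairs. Sign accuracy is the
#' fraction of true positives whose predicted coefficient sign matches the
#' planted effect sign. With no predictions, recall is 0 and precision/FDR
#' are undefined (\code{NA}, flagged).
#'
#' @param predicted data.frame with \code{gene_id}, an element column
#'   (\code{peak_id} or \code{tf_id}) and \code{beta}
#' @param truth matching truth data.frame with the same keys and
#'   \code{effect}
#' @return list: recall, precision, fdr, sign_accuracy, tp, fp, fn, flagged
#' @export
evaluateRecovery <- function(predicted, truth) {
  elem <- intersect(c("peak_id", "tf_id"), intersect(names(predicted),
                                                     names(truth)))
  if (length(elem) == 0L) stop("no shared element column (peak_id or tf_id)")
  elem <- elem[1]
  pkey <- paste(predicted$gene_id, predicted[[elem]])
  tkey <- paste(truth$gene_id, truth[[elem]])
  tp_mask <- pkey %in% tkey
  tp <- sum(tp_mask); fp <- sum(!tp_mask); fn <- sum(!tkey %in% pkey)
  if (nrow(predicted) == 0L) {
    return(list(recall = 0, precision = NA_real_, fdr = NA_real_,
                sign_accuracy = NA_real_, tp = 0L, fp = 0L,
                fn = length(tkey), flagged = TRUE))
  }
  sgn <- if (tp > 0) {
    mean(sign(predicted$beta[tp_mask]) ==
           sign(truth$effect[match(pkey[tp_mask], tkey)]))
  } else NA_real_
  list(recall = tp / length(tkey), precision = tp / nrow(predicted),
       fdr = fp / nrow(predicted), sign_accuracy = sgn,
       tp = tp, fp = fp, fn = fn, flagged = FALSE)
}
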