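#' Apportion counts to classes by largest remainder
#'
#' Deterministically turns fractional class proportions into integer counts
#' that sum exactly to `n`: each class gets `floor(n * p)` and the leftover
#' units go to the classes with the largest fractional remainders (ties broken
#' by class order).
#'
#' @param n Total count to apportion.
#' @param props Numeric vector of proportions summing to 1.
#' @return Integer vector of the same length as `props` summing to `n`.
#' @keywords internal
largest_remainder <- function(n, props) {
  if (abs(sum(props) - 1) > 1e-9) {
    od_config_error("class proportions must sum to 1 (got ", sum(props), ")")
  }
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    frac <- raw - base
    take <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

deg_classes <- c(
  "consistent", "opposite",
  "inconsistent_human_only", "inconsistent_mouse_only", "null"
)

#' Simulate a paired two-species differential-expression experiment
#'
#' Generates negative-binomial count matrices for a case/control contrast in
#' two species over the same set of ortholog genes, with a planted
#' cross-species regulation class per gene.  `consistent` genes are regulated
#' with the same fold-change sign in both species, `opposite` genes with
#' opposing signs, `inconsistent_*` genes are regulated in one species and
#' flat in the other, and `null` genes are flat in both.  Fold-change
#' magnitudes (log2 units) are lognormal; per-gene baseline means are
#' lognormal; counts are negative-binomial with a shared dispersion, and the
#' case/control mean ratio per gene equals `2^lfc`, applied symmetrically
#' (`2^(-lfc/2)` to controls and `2^(+lfc/2)` to cases) so the planted value
#' is the group-mean log2 ratio.
#'
#' Class counts follow largest-remainder apportionment of `props`, so they sum
#' exactly to `n_genes`.  Human gene symbols are upper-case (`GENE0001`),
#' mouse symbols title-case (`Gene0001`), and the returned one-to-one ortholog
#' map pairs them, mirroring the human/mouse symbol convention.
#'
#' @param n_genes Number of ortholog genes.
#' @param props Named or ordered proportions for classes
#'   (consistent, opposite, inconsistent_human_only, inconsistent_mouse_only,
#'   null); must sum to 1.
#' @param lfc_magnitude_mean Median of the lognormal |log2FC| magnitude
#'   distribution (log2 units).
#' @param lfc_magnitude_sd Lognormal sdlog of the magnitude distribution;
#'   0 plants the same magnitude everywhere.
#' @param n_samples_per_group Samples per group (control, case) per species.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the per-gene
#'   baseline mean count.
#' @param seed Integer seed; all draws come from named RNG streams derived
#'   from it, so outputs are bit-reproducible.
#' @return A list with `human` and `mouse` integer count matrices
#'   (genes x 2*n_samples_per_group; controls first), `groups` (factor,
#'   levels control/case), `truth` (data.frame: gene_id, true_class,
#'   human_lfc, mouse_lfc) and `ortholog_map` (data.frame: human_symbol,
#'   mouse_symbol).
#' @examples
#' sim <- simulate_deg_pair(n_genes = 50, n_samples_per_group = 3, seed = 1)
#' table(sim$truth$true_class)
#' @export
simulate_deg_pair <- function(n_genes,
                              props = c(consistent = 0.10, opposite = 0.10,
                                        inconsistent_human_only = 0.10,
                                        inconsistent_mouse_only = 0.10,
                                        null = 0.60),
                              lfc_magnitude_mean = 1.5,
                              lfc_magnitude_sd = 0.3,
                              n_samples_per_group = 10,
                              dispersion = 0.1,
                              baseline_meanlog = log(300),
                              baseline_sdlog = 0.8,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_samples_per_group >= 2, dispersion > 0,
            length(props) == 5)
  if (n_genes < sum(props > 0)) {
    od_config_error("n_genes is smaller than the number of nonzero classes")
  }
  counts <- largest_remainder(n_genes, props)
  true_class <- factor(rep(deg_classes, counts), levels = deg_classes)

  with_stream(seed, "deg_pair", {
    mag_h <- rlnorm(n_genes, meanlog = log(lfc_magnitude_mean),
                    sdlog = lfc_magnitude_sd)
    mag_m <- rlnorm(n_genes, meanlog = log(lfc_magnitude_mean),
                    sdlog = lfc_magnitude_sd)
    sign_h <- sample(c(-1, 1), n_genes, replace = TRUE)
    sign_flip <- sample(c(-1, 1), n_genes, replace = TRUE) # for inconsistent genes

    human_lfc <- numeric(n_genes)
    mouse_lfc <- numeric(n_genes)
    is <- true_class == "consistent"
    human_lfc[is] <- sign_h[is] * mag_h[is]
    mouse_lfc[is] <- sign_h[is] * mag_m[is]
    is <- true_class == "opposite"
    human_lfc[is] <- sign_h[is] * mag_h[is]
    mouse_lfc[is] <- -sign_h[is] * mag_m[is]
    is <- true_class == "inconsistent_human_only"
    human_lfc[is] <- sign_flip[is] * mag_h[is]
    is <- true_class == "inconsistent_mouse_only"
    mouse_lfc[is] <- sign_flip[is] * mag_m[is]

    mu0_h <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    mu0_m <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)

    n2 <- 2L * n_samples_per_group
    groups <- factor(rep(c("control", "case"), each = n_samples_per_group),
                     levels = c("control", "case"))
    nb_matrix <- function(mu0, lfc) {
      mu <- cbind(
        matrix(mu0 * 2^(-lfc / 2), n_genes, n_samples_per_group),
        matrix(mu0 * 2^(+lfc / 2), n_genes, n_samples_per_group)
      )
      m <- matrix(rnbinom(n_genes * n2, mu = as.vector(mu),
                          size = 1 / dispersion),
                  nrow = n_genes)
      storage.mode(m) <- "integer"
      m
    }
    human <- nb_matrix(mu0_h, human_lfc)
    mouse <- nb_matrix(mu0_m, mouse_lfc)

    ids <- sprintf("%04d", seq_len(n_genes))
    h_sym <- paste0("GENE", ids)
    m_sym <- paste0("Gene", ids)
    dimnames(human) <- list(h_sym, paste0("h_", groups, seq_len(n2)))
    dimnames(mouse) <- list(m_sym, paste0("m_", groups, seq_len(n2)))

    list(
      human = human, mouse = mouse, groups = groups,
      truth = data.frame(gene_id = h_sym, true_class = true_class,
                         human_lfc = human_lfc, mouse_lfc = mouse_lfc,
                         stringsAsFactors = FALSE),
      ortholog_map = data.frame(human_symbol = h_sym, mouse_symbol = m_sym,
                                stringsAsFactors = FALSE)
    )
  })
}

#' Simulate an expression matrix with planted lncRNA-coding modules
#'
#' Builds a samples-by-genes design where each lncRNA and its planted coding
#' partners load on a shared latent factor: for member rows,
#' `x = latent_correlation * z + noise_sd * eps` with `z` the module's latent
#' factor and `eps` iid standard normal, so the population correlation between
#' any two members is `latent_correlation^2 / (latent_correlation^2 +
#' noise_sd^2)`.  Coding genes outside every module are independent standard
#' normal noise.
#'
#' @param n_lnc Number of lncRNAs (one planted module each).
#' @param n_coding Number of coding genes; must be at least
#'   `n_lnc * module_size`.
#' @param n_samples Number of samples (columns).
#' @param module_size Coding partners per lncRNA; member sets are disjoint.
#' @param latent_correlation Loading on the shared factor, in (0, 1].
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed (named-stream RNG).
#' @return A list with `matrix` (genes x samples, lncRNA rows first),
#'   `lnc_ids`, `coding_ids`, and `truth` — a data.frame of planted
#'   (lnc_id, coding_id) edges.
#' @export
simulate_coexpression <- function(n_lnc, n_coding, n_samples,
                                  module_size,
                                  latent_correlation = 0.99,
                                  noise_sd = 0.1,
                                  seed = 1L) {
  stopifnot(n_lnc >= 1, n_samples >= 2, module_size >= 1,
            latent_correlation > 0 || latent_correlation == 0,
            noise_sd > 0)
  if (module_size * n_lnc > n_coding) {
    od_config_error("module_size * n_lnc (", module_size * n_lnc,
                    ") exceeds n_coding (", n_coding, ")")
  }
  lnc_ids <- sprintf("lnc%03d", seq_len(n_lnc))
  coding_ids <- sprintf("coding%04d", seq_len(n_coding))
  with_stream(seed, "coexpression", {
    mat <- matrix(0, nrow = n_lnc + n_coding, ncol = n_samples,
                  dimnames = list(c(lnc_ids, coding_ids), NULL))
    truth <- vector("list", n_lnc)
    member_of <- rep(NA_integer_, n_coding)
    # disjoint member sets drawn at random from the coding pool, so two
    # simulated species (different seeds) plant different modules
    pool <- sample.int(n_coding)
    for (i in seq_len(n_lnc)) {
      members <- sort(pool[((i - 1L) * module_size + 1L):(i * module_size)])
      member_of[members] <- i
      z <- rnorm(n_samples)
      mat[i, ] <- latent_correlation * z + noise_sd * rnorm(n_samples)
      for (j in members) {
        mat[n_lnc + j, ] <- latent_correlation * z + noise_sd * rnorm(n_samples)
      }
      truth[[i]] <- data.frame(lnc_id = lnc_ids[i],
                               coding_id = coding_ids[members],
                               stringsAsFactors = FALSE)
    }
    noise_rows <- which(is.na(member_of))
    for (j in noise_rows) {
      mat[n_lnc + j, ] <- rnorm(n_samples)
    }
    colnames(mat) <- sprintf("s%03d", seq_len(n_samples))
    list(matrix = mat, lnc_ids = lnc_ids, coding_ids = coding_ids,
         truth = do.call(rbind, truth))
  })
}

#' Simulate pairs of lncRNA transcript sequences at controlled divergence
#'
#' Conserved pairs are a random nucleotide sequence plus a copy mutated by
#' independent per-base substitution (always to a different base); the
#' remaining pairs are two independent uniform-random sequences.  The number
#' of conserved pairs is `round(n_pairs * conserved_fraction)` and they come
#' first, recorded in the truth table.
#'
#' @param n_pairs Number of query/subject pairs.
#' @param conserved_fraction Fraction of pairs that share ancestry, in [0,1].
#' @param length Sequence length in bases (>= 60 so an alignment longer than
#'   50 columns is attainable).
#' @param substitution_rate Per-base substitution probability for conserved
#'   pairs, in [0,1].
#' @param seed Integer seed (named-stream RNG).
#' @return A list with `query` and `subject` named character vectors and
#'   `truth` (data.frame: query_id, subject_id, conserved).
#' @export
simulate_sequence_pairs <- function(n_pairs, conserved_fraction = 0.25,
                                    length = 300, substitution_rate = 0.05,
                                    seed = 1L) {
  stopifnot(n_pairs >= 1, conserved_fraction >= 0, conserved_fraction <= 1,
            substitution_rate >= 0, substitution_rate <= 1)
  if (length < 60) {
    od_config_error("sequence length must be >= 60")
  }
  n_cons <- round(n_pairs * conserved_fraction)
  bases <- c("A", "C", "G", "T")
  with_stream(seed, "sequence_pairs", {
    query <- character(n_pairs)
    subject <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      q <- sample(bases, length, replace = TRUE)
      if (i <= n_cons) {
        s <- q
        hit <- which(runif(length) < substitution_rate)
        for (k in hit) {
          s[k] <- sample(setdiff(bases, q[k]), 1L)
        }
      } else {
        s <- sample(bases, length, replace = TRUE)
      }
      query[i] <- paste(q, collapse = "")
      subject[i] <- paste(s, collapse = "")
    }
    qid <- sprintf("hlnc%03d", seq_len(n_pairs))
    sid <- sprintf("mlnc%03d", seq_len(n_pairs))
    names(query) <- qid
    names(subject) <- sid
    list(query = query, subject = subject,
         truth = data.frame(query_id = qid, subject_id = sid,
                            conserved = seq_len(n_pairs) <= n_cons,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a chimeric (two-species) count table with prefixed gene IDs
#'
#' Emulates quantification against a concatenated human+mouse reference whose
#' annotations carry a `human_`/`mouse_` species prefix, as used for chimeric
#' humanized-liver RNA-seq.  Counts are negative-binomial with lognormal
#' per-gene means.
#'
#' @param n_human_genes,n_mouse_genes Genes per species (positive).
#' @param n_samples Number of samples (positive).
#' @param dispersion Negative-binomial dispersion.
#' @param seed Integer seed (named-stream RNG).
#' @return A list with `counts` (integer matrix whose row names carry the
#'   species prefix) and `species` (character vector of truth labels,
#'   "human"/"mouse", parallel to rows).
#' @export
simulate_chimeric_counts <- function(n_human_genes, n_mouse_genes, n_samples,
                                     dispersion = 0.1, seed = 1L) {
  if (n_human_genes < 1 || n_mouse_genes < 1) {
    od_config_error("gene counts must be positive")
  }
  if (n_samples < 1) {
    od_config_error("n_samples must be positive")
  }
  n <- n_human_genes + n_mouse_genes
  with_stream(seed, "chimeric", {
    mu <- rlnorm(n, log(200), 1)
    m <- matrix(rnbinom(n * n_samples, mu = rep(mu, n_samples),
                        size = 1 / dispersion),
                nrow = n)
    storage.mode(m) <- "integer"
    species <- rep(c("human", "mouse"), c(n_human_genes, n_mouse_genes))
    rownames(m) <- paste0(
      species, "_",
      c(paste0("GENE", sprintf("%04d", seq_len(n_human_genes))),
        paste0("Gene", sprintf("%04d", seq_len(n_mouse_genes))))
    )
    colnames(m) <- sprintf("s%02d", seq_len(n_samples))
    list(counts = m, species = species)
  })
}
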