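# Independent brute-force oracles and tiny fixture builders. These
# re-derive every statistic from its definition with literal loops; they
# deliberately share no code with the package internals.

toy_matrix <- function(p, n, seed) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%03d", seq_len(n))))
}

oracle_kernel_z <- function(m, factor = 1 / 4) {
  z <- m
  for (i in seq_len(nrow(m))) {
    s <- sd(m[i, ])
    if (s == 0) {
      z[i, ] <- 0.5
    } else {
      h <- s * factor
      for (j in seq_len(ncol(m))) {
        acc <- 0
        for (k in seq_len(ncol(m))) {
          acc <- acc + pnorm((m[i, j] - m[i, k]) / h)
        }
        z[i, j] <- acc / ncol(m)
      }
    }
  }
  z
}

# literal step-by-step weighted KS walk, one sample at a time
oracle_gsva <- function(m, set_genes, tau = 1,
                        mode = "magnitude_difference", factor = 1 / 4) {
  z <- oracle_kernel_z(m, factor)
  p <- nrow(m)
  out <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    ord <- order(-z[, j], rownames(m))
    ranked <- rownames(m)[ord]
    inset <- ranked %in% set_genes
    msize <- sum(inset)
    w <- abs(p / 2 - seq_len(p))^tau
    wsum <- sum(w[inset])
    nu <- numeric(p)
    running_w <- 0
    n_in <- 0
    n_out <- 0
    for (l in seq_len(p)) {
      if (inset[l]) {
        running_w <- running_w + w[l]
        n_in <- n_in + 1
      } else {
        n_out <- n_out + 1
      }
      p_in <- if (wsum > 0) running_w / wsum else n_in / msize
      nu[l] <- p_in - n_out / (p - msize)
    }
    out[j] <- if (mode == "magnitude_difference") {
      max(0, max(nu)) + min(0, min(nu))
    } else {
      nu[which.max(abs(nu))]
    }
  }
  out
}

oracle_ssgsea <- function(m, set_genes, alpha = 0.25) {
  p <- nrow(m)
  out <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], rownames(m))
    ranked <- rownames(m)[ord]
    inset <- ranked %in% set_genes
    msize <- sum(inset)
    r <- p - seq_len(p) + 1
    denom <- sum((r[inset])^alpha)
    acc <- 0
    p_in <- 0
    p_out <- 0
    for (l in seq_len(p)) {
      if (inset[l]) p_in <- p_in + r[l]^alpha / denom
      else p_out <- p_out + 1 / (p - msize)
      acc <- acc + (p_in - p_out)
    }
    out[j] <- acc
  }
  out
}

# step-up FDR rule evaluated directly from its definition
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    candidates <- vapply(seq_len(m), function(j) {
      if (ps[j] >= pi) ps[j] * m / j else Inf
    }, numeric(1))
    min(1, min(candidates))
  }, numeric(1))
}

oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

oracle_logrank <- function(time, event, group) {
  levels <- sort(unique(group))
  stopifnot(length(levels) == 2L)
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == levels[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O1 - E1)^2 / V
  list(O1 = O1, E1 = E1, chi = chi,
       p = pchisq(chi, df = 1, lower.tail = FALSE))
}

# quadratic all-pairs overlap test on half-open intervals
oracle_any_overlap <- function(a, b, window = 0) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- FALSE
    for (k in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[k] &&
          (a$start[i] - window) < (b$end[k] + window) &&
          (b$start[k] - window) < (a$end[i] + window)) {
        hit <- TRUE
        break
      }
    }
    hit
  }, logical(1))
}

oracle_tmb <- function(maf) {
  truncating <- c("Nonsense_Mutation", "Frame_Shift_Del",
                  "Frame_Shift_Ins", "Splice_Site")
  non_truncating <- c("Missense_Mutation", "In_Frame_Del",
                      "In_Frame_Ins", "Nonstop_Mutation")
  samples <- unique(maf$sample_id)
  out <- data.frame(sample_id = samples, tmb = NA_real_)
  for (k in seq_along(samples)) {
    rows <- maf[maf$sample_id == samples[k], , drop = FALSE]
    nt <- sum(rows$variant_classification %in% truncating)
    nn <- sum(rows$variant_classification %in% non_truncating)
    out$tmb[k] <- 2 * nt + nn
  }
  out
}

# small single-cell counts fixture with known QC outcomes
toy_sc_counts <- function(seed = 7) {
  set.seed(seed)
  p <- 60; n <- 30
  m <- matrix(rpois(p * n, 3), p, n,
              dimnames = list(c(sprintf("MT-%02d", 1:5),
                                sprintf("C%03d", 1:(p - 5))),
                              sprintf("cell%02d", seq_len(n))))
  m
}
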