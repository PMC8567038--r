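#' ERP component window definition
#'
#' Names a component, its ms analysis window (half-open) and its electrode
#' cluster. Defaults for the three components of interest: P2 and LPC over a
#' fronto-central cluster, P3 over a centro-parietal cluster.
#'
#' @param name component name (`"P2"`, `"P3"`, `"LPC"`, or custom).
#' @param window ms interval, half-open.
#' @param electrodes electrode labels of the analysis cluster.
#' @return object of class `component_window`.
#' @export
component_window <- function(name, window, electrodes) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("`window` must be c(start_ms, end_ms)")
  structure(list(name = name, window = as.numeric(window),
                 electrodes = as.character(electrodes)),
            class = "component_window")
}

#' Default component windows
#'
#' P2: 140-200 ms, P3: 300-400 ms, LPC: 500-700 ms, with the conventional
#' fronto-central (P2/LPC) and centro-parietal (P3) eight-electrode clusters.
#'
#' @return named list of [component_window()] objects.
#' @export
default_component_windows <- function() {
  fc <- c("F3", "F4", "FC1", "FC2", "Fz", "C3", "C4", "Cz")
  cp <- c("C3", "C4", "CP1", "CP2", "Cz", "P3", "P4", "Pz")
  list(P2  = component_window("P2",  c(140, 200), fc),
       P3  = component_window("P3",  c(300, 400), cp),
       LPC = component_window("LPC", c(500, 700), fc))
}

#' Grand-average ERP waveforms by condition
#'
#' Arithmetic mean over trials within each condition. When participant ids
#' are attached, trials are first averaged within participant and the
#' participant means are then averaged, so every participant contributes
#' equally regardless of surviving trial counts.
#'
#' @param epochs an [epoch_array()] with condition labels.
#' @return named list (one per condition) of channels x samples matrices,
#'   with attributes `fs`, `window`, `channel_labels`.
#' @export
grand_average <- function(epochs) {
  if (is.null(epochs$condition_labels))
    stop("epochs carry no condition labels")
  conds <- unique(epochs$condition_labels)
  out <- lapply(conds, function(cond) {
    idx <- which(epochs$condition_labels == cond)
    if (!length(idx)) stop("condition ", cond, " has no trials")
    if (!is.null(epochs$participant_ids)) {
      pids <- unique(epochs$participant_ids[idx])
      per <- lapply(pids, function(p) {
        i <- idx[epochs$participant_ids[idx] == p]
        apply(epochs$data[i, , , drop = FALSE], c(2, 3), mean)
      })
      Reduce(`+`, per) / length(per)
    } else {
      apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    }
  })
  names(out) <- conds
  for (k in seq_along(out)) rownames(out[[k]]) <- epochs$channel_labels
  attr(out, "fs") <- epochs$fs
  attr(out, "window") <- epochs$window
  attr(out, "channel_labels") <- epochs$channel_labels
  out
}

#' Mean component amplitude per participant, condition and electrode
#'
#' Averages each trial's amplitude over the component's half-open ms window,
#' then averages trials within participant x condition, returning one long
#' row per participant x condition x electrode cell — the fully crossed table
#' a within-subjects ANOVA consumes. Without participant ids every trial is
#' treated as its own participant (trial-level table).
#'
#' @param epochs an [epoch_array()] with condition labels.
#' @param window a [component_window()].
#' @return data.frame with columns `participant`, `condition`, `electrode`,
#'   `amplitude` (uV).
#' @export
mean_amplitude <- function(epochs, window) {
  stopifnot(inherits(window, "component_window"))
  missing <- setdiff(window$electrodes, epochs$channel_labels)
  if (length(missing))
    stop("electrode(s) absent from montage: ", paste(missing, collapse = ", "))
  if (is.null(epochs$condition_labels))
    stop("epochs carry no condition labels")
  idx <- ms_to_samples(epochs, window$window)
  ch <- match(window$electrodes, epochs$channel_labels)
  pid <- epochs$participant_ids
  if (is.null(pid)) pid <- sprintf("t%05d", seq_len(n_trials(epochs)))
  # trial x electrode window means
  tw <- apply(epochs$data[, ch, idx, drop = FALSE], c(1, 2), mean)
  cells <- expand.grid(participant = unique(pid),
                       condition = unique(epochs$condition_labels),
                       electrode = window$electrodes,
                       stringsAsFactors = FALSE)
  cells$amplitude <- mapply(function(p, cond, e) {
    i <- which(pid == p & epochs$condition_labels == cond)
    if (!length(i)) return(NA_real_)
    mean(tw[i, match(e, window$electrodes)])
  }, cells$participant, cells$condition, cells$electrode)
  cells
}

#' Peak latency within a component window
#'
#' Time (ms) of the maximum amplitude of one electrode's waveform within the
#' window; ties resolve to the earliest sample. A flat window (zero range) is
#' flagged indeterminate.
#'
#' @param waveform channels x samples matrix (a [grand_average()] element).
#' @param electrode electrode label (must be a rowname of `waveform`).
#' @param window ms interval.
#' @param fs,epoch_window sampling rate and epoch window; defaults read from
#'   the attributes [grand_average()] attaches.
#' @return `list(latency_ms =, amplitude =, indeterminate =)`.
#' @export
peak_latency <- function(waveform, electrode, window,
                         fs = attr(waveform, "fs"),
                         epoch_window = attr(waveform, "window")) {
  if (!electrode %in% rownames(waveform))
    stop("electrode ", electrode, " not present")
  fake <- list(fs = fs, window = epoch_window)
  idx <- ms_to_samples(fake, window)
  x <- waveform[electrode, idx]
  flat <- diff(range(x)) == 0
  k <- which.max(x)  # earliest on ties
  t_ms <- epoch_window[1] + (idx[k] - 1) * 1000 / fs
  list(latency_ms = t_ms, amplitude = x[k], indeterminate = flat)
}

orthonormal_contrasts <- function(K) {
  M <- stats::contr.helmert(K)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

# Greenhouse-Geisser epsilon for an effect with contrast matrix C applied to
# the S x (cells) matrix of per-subject scores:
# epsilon = tr(E)^2 / (d * tr(E^2)), E = cov(scores %*% C), d = ncol(C);
# bounded to [1/d, 1].
gg_epsilon <- function(scores, C = orthonormal_contrasts(ncol(scores))) {
  d <- ncol(C)
  if (d <= 1L) return(1)
  E <- stats::cov(scores %*% C)
  eps <- sum(diag(E))^2 / (d * sum(E^2))
  min(max(eps, 1 / d), 1)
}

#' Two-way fully within-subjects repeated-measures ANOVA
#'
#' Fits the 2 (condition) x K (electrode) within-subjects ANOVA on a long
#' amplitude table via the classical sums-of-squares decomposition: each
#' effect is tested against its own effect-by-subject interaction. Reports
#' F, raw and Greenhouse-Geisser-adjusted degrees of freedom and p-values,
#' the Greenhouse-Geisser epsilon (from the orthonormal-contrast covariance),
#' and partial eta squared. The correction is applied to factors with more
#' than two levels; a 2-level factor has epsilon = 1 by construction.
#'
#' @param table data.frame with columns `participant`, `condition`,
#'   `electrode`, `amplitude` — fully crossed, >= 2 participants.
#' @return data.frame of class `anova_result`, one row per effect
#'   (`condition`, `electrode`, `condition:electrode`) with columns `F`,
#'   `df1`, `df2`, `epsilon`, `df1_gg`, `df2_gg`, `p`, `p_gg`, `pes`.
#' @export
rm_anova_2xK <- function(table) {
  req <- c("participant", "condition", "electrode", "amplitude")
  if (!all(req %in% names(table)))
    stop("table needs columns: ", paste(req, collapse = ", "))
  if (anyNA(table$amplitude)) stop("missing cells: design must be fully crossed")
  subs <- unique(table$participant)
  conds <- unique(table$condition)
  elecs <- unique(table$electrode)
  S <- length(subs); A <- length(conds); K <- length(elecs)
  if (S < 2L) stop("need >= 2 participants")
  Y <- array(NA_real_, dim = c(S, A, K))
  for (r in seq_len(nrow(table))) {
    Y[match(table$participant[r], subs),
      match(table$condition[r], conds),
      match(table$electrode[r], elecs)] <- table$amplitude[r]
  }
  if (anyNA(Y)) stop("missing cells: design must be fully crossed")

  gm <- mean(Y)
  m_s  <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  ss_a  <- S * K * sum((m_a - gm)^2)
  ss_b  <- S * A * sum((m_b - gm)^2)
  ss_ab <- S * sum((m_ab - outer(m_a, rep(1, K)) -
                      outer(rep(1, A), m_b) + gm)^2)
  ss_as <- K * sum((m_sa - outer(m_s, rep(1, A)) -
                      outer(rep(1, S), m_a) + gm)^2)
  ss_bs <- A * sum((m_sb - outer(m_s, rep(1, K)) -
                      outer(rep(1, S), m_b) + gm)^2)
  resid <- Y
  for (s in seq_len(S)) for (a in seq_len(A)) for (b in seq_len(K))
    resid[s, a, b] <- Y[s, a, b] - m_sa[s, a] - m_sb[s, b] - m_ab[a, b] +
      m_s[s] + m_a[a] + m_b[b] - gm
  ss_abs <- sum(resid^2)

  eff <- data.frame(
    effect = c("condition", "electrode", "condition:electrode"),
    ss = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_as, ss_bs, ss_abs),
    df1 = c(A - 1, K - 1, (A - 1) * (K - 1)),
    df2 = c((A - 1) * (S - 1), (K - 1) * (S - 1), (A - 1) * (K - 1) * (S - 1)),
    stringsAsFactors = FALSE)
  eff$F <- (eff$ss / eff$df1) / (eff$ss_err / eff$df2)
  eff$F[eff$ss == 0] <- 0          # a null effect is 0 even when its error stratum is empty
  eff$pes <- ifelse(eff$ss + eff$ss_err > 0, eff$ss / (eff$ss + eff$ss_err), 0)

  cells <- matrix(Y, S, A * K)  # column order: a varies fastest, then b
  C_ab <- kronecker(orthonormal_contrasts(K), orthonormal_contrasts(A))
  eff$epsilon <- c(
    gg_epsilon(m_sa),        # condition (A levels; = 1 when A = 2)
    gg_epsilon(m_sb),        # electrode (K levels)
    gg_epsilon(cells, C_ab)  # interaction
  )
  eff$df1_gg <- eff$df1 * eff$epsilon
  eff$df2_gg <- eff$df2 * eff$epsilon
  eff$p    <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$p_gg <- stats::pf(eff$F, eff$df1_gg, eff$df2_gg, lower.tail = FALSE)
  out <- eff[, c("effect", "F", "df1", "df2", "epsilon", "df1_gg", "df2_gg",
                 "p", "p_gg", "pes")]
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Per-electrode post-hoc condition contrasts
#'
#' Paired t-tests of the two conditions at each electrode. No multiplicity
#' adjustment by default; `adjust = "bonferroni"` (or any [stats::p.adjust()]
#' method) is available.
#'
#' @param table amplitude table as for [rm_anova_2xK()] (exactly 2 conditions).
#' @param adjust p-adjustment method, default `"none"`.
#' @param alpha significance level for the `significant` flag, default 0.05.
#' @return data.frame with per-electrode mean difference (first condition
#'   minus second), t, df, p, adjusted p and significance flag.
#' @export
posthoc_by_electrode <- function(table, adjust = "none", alpha = 0.05) {
  conds <- unique(table$condition)
  if (length(conds) != 2L) stop("post-hoc contrasts need exactly 2 conditions")
  subs <- unique(table$participant)
  if (length(subs) < 2L) stop("need >= 2 participants")
  elecs <- unique(table$electrode)
  res <- lapply(elecs, function(e) {
    x <- vapply(subs, function(p) table$amplitude[table$participant == p &
                  table$condition == conds[1] & table$electrode == e][1], 0)
    y <- vapply(subs, function(p) table$amplitude[table$participant == p &
                  table$condition == conds[2] & table$electrode == e][1], 0)
    d <- x - y
    if (stats::sd(d) < 1e-12) {
      # identical conditions: no evidence of a difference by construction
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
    }
    data.frame(electrode = e, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < alpha
  attr(out, "contrast") <- paste(conds[1], "-", conds[2])
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's convention), ties receive average
#' ranks, and the normal-approximation Z uses a continuity correction with the
#' classical variance `n(n+1)(2n+1)/24` (Wilcoxon's original approximation;
#' no tie adjustment). The two-sided p-value is exact (from the signed-rank
#' distribution) when `n <= exact_limit` and no ties or zeros are present,
#' otherwise it comes from the normal approximation.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param exact_limit largest n for which the exact null distribution is used
#'   (default 25).
#' @return `list(statistic = W+ (sum of positive-difference ranks), Z =,
#'   p =, n = pairs used, exact = logical)`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  cc <- sign(W - mu) * 0.5
  Z <- (W - mu - cc) / sqrt(sigma2)
  has_ties <- anyDuplicated(r) > 0
  exact <- n <= exact_limit && !has_ties
  if (exact) {
    # two-sided exact p from the signed-rank null distribution
    p_low  <- stats::psignrank(W, n)
    p_high <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
  }
  list(statistic = W, Z = Z, p = p, n = n, exact = exact)
}

#' Behavioural response-time summary and paired test
#'
#' Summarises responded-trial RTs per condition (mean, SD, median, response
#' rate) and runs the Wilcoxon signed-rank test on trial-paired RTs (trials
#' where either condition lacks a response are dropped from the pairing).
#'
#' @param behavior table from [simulate_behavior()] / [read_behavior()].
#' @param conditions the two condition labels to compare, default HAI vs LAI
#'   (so a positive effect means slower responses under high load).
#' @return `list(summary = data.frame, test = wilcoxon result)`.
#' @export
behavior_stats <- function(behavior, conditions = c("HAI", "LAI")) {
  stopifnot(all(conditions %in% behavior$condition))
  summ <- do.call(rbind, lapply(conditions, function(cond) {
    b <- behavior[behavior$condition == cond, ]
    rt <- b$rt_ms[b$responded]
    data.frame(condition = cond, n = nrow(b), n_responded = sum(b$responded),
               mean_rt = mean(rt), sd_rt = stats::sd(rt),
               median_rt = stats::median(rt),
               response_rate = mean(b$responded), stringsAsFactors = FALSE)
  }))
  a <- behavior[behavior$condition == conditions[1], ]
  b <- behavior[behavior$condition == conditions[2], ]
  ids <- intersect(a$trial_id[a$responded], b$trial_id[b$responded])
  x <- a$rt_ms[match(ids, a$trial_id)]
  y <- b$rt_ms[match(ids, b$trial_id)]
  list(summary = summ, test = wilcoxon_signed_rank(x, y))
}
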