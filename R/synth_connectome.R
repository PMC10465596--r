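#' Population specification for the synthetic connectome generator
#'
#' Describes the statistical structure of a generated antennal-lobe circuit:
#' a planted "patchy" peptidergic LN ensemble of `n_patchy_lns` neurons that
#' innervates glomerulus g with probability `p[g]` and whose intraglomerular
#' input:output ratio is planted at `r[g]`, a background of `n_other_lns`
#' local interneurons of mixed subtypes, per-glomerulus OSN and uniglomerular
#' PN residents, and one modulatory marker neuron ("CSD") that contacts the
#' planted ensemble. Defaults emulate the biological study conditions: a
#' 9-neuron target ensemble within ~200 AL local interneurons.
#'
#' @param n_glomeruli number of glomeruli.
#' @param n_patchy_lns size of the planted patchy ensemble (default 9).
#' @param n_other_lns background LNs (default 191, so LN total is ~200).
#' @param n_osns_per_glomerulus,n_upns_per_glomerulus resident counts.
#' @param p per-glomerulus innervation probability (recycled to length
#'   `n_glomeruli`).
#' @param r planted per-glomerulus input:output ratio in \[-1, 1\] (recycled).
#' @param syn_per_glomerulus connections a planted LN makes per innervated
#'   glomerulus.
#' @param transmitter_mix named list of per-category probability vectors over
#'   transmitter classes.
#' @param seed integer master seed (mandatory).
#' @return an object of class `al_population_spec`.
#' @export
population_spec <- function(n_glomeruli = 10L, n_patchy_lns = 9L,
                            n_other_lns = 191L,
                            n_osns_per_glomerulus = 4L,
                            n_upns_per_glomerulus = 2L,
                            p = 0.5, r = 0.4, syn_per_glomerulus = 30L,
                            transmitter_mix = NULL, seed) {
  al_assert(!missing(seed), "al_spec_error", "population_spec: seed is mandatory")
  p <- rep_len(p, n_glomeruli)
  r <- rep_len(r, n_glomeruli)
  al_assert(all(p >= 0 & p <= 1), "al_spec_error",
            "innervation probabilities must lie in [0, 1]")
  al_assert(all(r >= -1 & r <= 1), "al_spec_error",
            "planted input:output ratios must lie in [-1, 1]")
  if (is.null(transmitter_mix)) {
    transmitter_mix <- list(
      OSN = c(excitatory = 1),
      uPN = c(excitatory = 1),
      LN = c(inhibitory = 0.9, excitatory = 0.1),
      other = c(modulatory = 1)
    )
  }
  structure(list(
    n_glomeruli = as.integer(n_glomeruli),
    n_patchy_lns = as.integer(n_patchy_lns),
    n_other_lns = as.integer(n_other_lns),
    n_osns_per_glomerulus = as.integer(n_osns_per_glomerulus),
    n_upns_per_glomerulus = as.integer(n_upns_per_glomerulus),
    p = p, r = r, syn_per_glomerulus = as.integer(syn_per_glomerulus),
    transmitter_mix = transmitter_mix, seed = as.integer(seed)
  ), class = "al_population_spec")
}

draw_class <- function(mix) {
  sample(names(mix), 1L, prob = mix)
}

# Short skeleton for a resident neuron: three nodes through its glomerulus.
resident_skeleton <- function(id, mesh) {
  pts <- sample_in_glomerulus(mesh, 3L)
  skeleton(id, data.frame(
    node_id = 1:3, parent_id = c(-1L, 1L, 2L),
    x = pts[, 1], y = pts[, 2], z = pts[, 3], radius = 100
  ))
}

# Patchy-LN arbor: a backbone polyline through the centroids of the innervated
# glomeruli (resampled every `spacing` nm) plus a small intraglomerular tuft
# per glomerulus. Geometry is sufficient for containment and flow-centrality
# work; no biophysical realism is claimed.
patchy_skeleton <- function(id, meshes, spacing = 2500, tuft_points = 4L,
                            offset = c(0, 0, 0)) {
  cents <- t(vapply(meshes, mesh_centroid, numeric(3)))
  cents <- cents[order(cents[, 1]), , drop = FALSE]
  pts <- cents[1, , drop = FALSE]
  if (nrow(cents) > 1) {
    for (i in 2:nrow(cents)) {
      a <- cents[i - 1, ]; b <- cents[i, ]
      len <- vec3_norm(b - a)
      nseg <- max(1L, ceiling(len / spacing))
      frac <- seq_len(nseg) / nseg
      pts <- rbind(pts, outer(frac, b - a) + matrix(a, nseg, 3, byrow = TRUE))
    }
  }
  nodes <- data.frame(
    node_id = seq_len(nrow(pts)),
    parent_id = c(-1L, seq_len(nrow(pts) - 1L)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3], radius = 150
  )
  # tufts: straight radial branchlets into each glomerulus from the nearest
  # backbone node (anchor -> midpoint -> tip per branchlet)
  for (m in meshes) {
    tp <- sample_in_glomerulus(m, tuft_points)
    ctr <- mesh_centroid(m)
    d2 <- (nodes$x - ctr[1])^2 + (nodes$y - ctr[2])^2 + (nodes$z - ctr[3])^2
    anchor <- nodes$node_id[which.min(d2)]
    apos <- unlist(nodes[nodes$node_id == anchor, c("x", "y", "z")])
    for (j in seq_len(tuft_points)) {
      mid <- (apos + tp[j, ]) / 2
      base <- nrow(nodes)
      nodes <- rbind(nodes, data.frame(
        node_id = base + 1:2, parent_id = c(anchor, base + 1L),
        x = c(mid[1], tp[j, 1]), y = c(mid[2], tp[j, 2]),
        z = c(mid[3], tp[j, 3]), radius = 80
      ))
    }
  }
  nodes$x <- nodes$x + offset[1]
  nodes$y <- nodes$y + offset[2]
  nodes$z <- nodes$z + offset[3]
  skeleton(id, nodes)
}

jitter_skeleton <- function(skel, id, sd = 200) {
  nd <- skel$nodes
  nd$x <- nd$x + stats::rnorm(nrow(nd), 0, sd)
  nd$y <- nd$y + stats::rnorm(nrow(nd), 0, sd)
  nd$z <- nd$z + stats::rnorm(nrow(nd), 0, sd)
  skeleton(id, nd)
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Builds the full circuit described by a [population_spec()]: glomerulus
#' meshes, resident OSNs/uPNs with home glomeruli, the planted patchy LN
#' ensemble (innervation Bernoulli(`p[g]`); within an innervated glomerulus the
#' planted input:output ratio `r[g]` is allocated by balanced rounding of
#' `syn_per_glomerulus`, so it is a structural property of the ensemble),
#' background LNs engineered to fail exactly one candidate-filter stage each,
#' a modulatory marker neuron ("CSD") contacting every planted LN at an
#' extraglomerular site, and a reference morphology library (jittered copies
#' of the planted arbors, standing in for driver-line light-microscopy images).
#'
#' Synapse sites are sampled uniformly inside the innervated glomerulus'
#' generating ellipsoid; output connectors are polyadic (up to three
#' postsynaptic partners share one presynaptic site).
#'
#' @param spec an `al_population_spec`.
#' @return a list with elements `connectome` (an `al_connectome`),
#'   `ground_truth` (planted ensemble ids, per-glomerulus planted counts and
#'   ratios, input polarity tallies, the planted innervation matrix) and
#'   `references` (list of reference `al_skeleton`s).
#' @export
make_connectome <- function(spec) {
  al_assert(inherits(spec, "al_population_spec"), "al_spec_error",
            "make_connectome expects a population_spec()")
  meshes <- make_glomeruli(spec$n_glomeruli,
                           seed = substream_seed(spec$seed, "glomeruli"))
  glom <- names(meshes)
  ann <- list()
  skels <- list()
  rows <- list()
  gt_counts <- list()
  gt_polarity <- list()
  connector_n <- 0L
  new_connectors <- function(k) {
    ids <- sprintf("cn%06d", connector_n + seq_len(k))
    connector_n <<- connector_n + k
    ids
  }
  annotate <- function(id, category, subtype, tclass, home = NA_character_,
                       status = "Traced") {
    ann[[length(ann) + 1L]] <<- data.frame(
      neuron_id = id, category = category, subtype = subtype,
      transmitter_class = tclass, home_glomerulus = home,
      tracing_status = status)
  }

  # residents: OSNs and uniglomerular PNs with home glomeruli
  residents <- list()
  for (g in glom) {
    with_seed(substream_seed(spec$seed, paste0("residents/", g)), {
      osn <- sprintf("OSN_%s_%02d", g, seq_len(spec$n_osns_per_glomerulus))
      upn <- sprintf("uPN_%s_%02d", g, seq_len(spec$n_upns_per_glomerulus))
      for (id in osn) {
        skels[[id]] <- resident_skeleton(id, meshes[[g]])
        annotate(id, "OSN", "sensory", draw_class(spec$transmitter_mix$OSN), g)
      }
      for (id in upn) {
        skels[[id]] <- resident_skeleton(id, meshes[[g]])
        annotate(id, "uPN", "projection", draw_class(spec$transmitter_mix$uPN), g)
      }
      residents[[g]] <- list(OSN = osn, uPN = upn)
    })
  }

  # marker neuron (serotonergic-modulatory, contacts the target ensemble)
  with_seed(substream_seed(spec$seed, "csd"), {
    skels[["CSD"]] <- skeleton("CSD", data.frame(
      node_id = 1:3, parent_id = c(-1L, 1L, 2L),
      x = c(0, 1e3, 2e3), y = c(0, 0, 0), z = c(0, 0, 0), radius = 200))
    annotate("CSD", "other", "modulatory_marker", "modulatory")
  })
  # a fixed extraglomerular site for marker synapses (box corner, outside all
  # meshes) so marker contacts never perturb planted per-glomerulus counts
  marker_site <- c(-5e3, -5e3, -5e3)

  add_ln_synapses <- function(ln_id, g_innervated, n_per_glom, ratio,
                              other_ln_pool) {
    for (g in g_innervated) {
      n_g <- n_per_glom
      rg <- ratio[[g]]
      frac <- n_g * (1 + rg) / 2
      n_in <- floor(frac) + stats::rbinom(1L, 1L, frac - floor(frac))
      n_in <- min(n_g, max(0L, n_in))
      n_out <- n_g - n_in
      res <- residents[[g]]
      pol <- c(excitatory = 0, inhibitory = 0, modulatory = 0, unknown = 0)
      if (n_in > 0) {
        pool_w <- c(0.5, 0.3, 0.2)
        kinds <- sample(c("OSN", "uPN", "LN"), n_in, replace = TRUE, prob = pool_w)
        partners <- vapply(kinds, function(k) {
          if (k == "LN" && length(other_ln_pool) > 0) sample(other_ln_pool, 1L)
          else sample(res[[if (k == "LN") "OSN" else k]], 1L)
        }, character(1))
        sites <- sample_in_glomerulus(meshes[[g]], n_in)
        cls <- ann_lookup_class(do.call(rbind, ann), partners)
        for (cl in cls) pol[[cl]] <- pol[[cl]] + 1
        rows[[length(rows) + 1L]] <<- data.frame(
          connector_id = new_connectors(n_in),
          pre_neuron = partners, post_neuron = ln_id,
          pre_x = sites[, 1] + 50, pre_y = sites[, 2], pre_z = sites[, 3],
          post_x = sites[, 1], post_y = sites[, 2], post_z = sites[, 3])
      }
      if (n_out > 0) {
        kinds <- sample(c("uPN", "OSN"), n_out, replace = TRUE, prob = c(0.6, 0.4))
        partners <- vapply(kinds, function(k) sample(res[[k]], 1L), character(1))
        # polyadic: consecutive outputs grouped <=3 per connector, one pre site
        grp <- rep(seq_len(n_out), each = 3L, length.out = n_out)
        grp <- as.integer(factor(grp, levels = unique(grp)))
        n_conn <- max(grp)
        conn_ids <- new_connectors(n_conn)
        pre_sites <- sample_in_glomerulus(meshes[[g]], n_conn)
        post_sites <- pre_sites[grp, , drop = FALSE] +
          matrix(stats::rnorm(3 * n_out, 0, 60), n_out, 3)
        rows[[length(rows) + 1L]] <<- data.frame(
          connector_id = conn_ids[grp],
          pre_neuron = ln_id, post_neuron = partners,
          pre_x = pre_sites[grp, 1], pre_y = pre_sites[grp, 2],
          pre_z = pre_sites[grp, 3],
          post_x = post_sites[, 1], post_y = post_sites[, 2],
          post_z = post_sites[, 3])
      }
      gt_counts[[length(gt_counts) + 1L]] <<- data.frame(
        neuron_id = ln_id, glomerulus = g, n_input = n_in, n_output = n_out,
        ratio = if (n_g > 0) (n_in - n_out) / (n_in + n_out) else NA_real_)
      gt_polarity[[length(gt_polarity) + 1L]] <<- data.frame(
        neuron_id = ln_id, glomerulus = g,
        class = names(pol), n = as.numeric(pol))
    }
  }

  add_marker_contact <- function(ln_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      connector_id = new_connectors(1L),
      pre_neuron = "CSD", post_neuron = ln_id,
      pre_x = marker_site[1], pre_y = marker_site[2], pre_z = marker_site[3],
      post_x = marker_site[1] + 100, post_y = marker_site[2],
      post_z = marker_site[3])
  }

  # planted patchy ensemble
  patchy_ids <- sprintf("pLN_%02d", seq_len(spec$n_patchy_lns))
  innervation <- matrix(0L, spec$n_patchy_lns, spec$n_glomeruli,
                        dimnames = list(patchy_ids, glom))
  for (i in seq_along(patchy_ids)) {
    id <- patchy_ids[i]
    with_seed(substream_seed(spec$seed, id), {
      inn <- stats::rbinom(spec$n_glomeruli, 1L, spec$p) == 1L
      if (!any(inn)) inn[sample(spec$n_glomeruli, 1L, prob = pmax(spec$p, 1e-9))] <- TRUE
      innervation[i, ] <- as.integer(inn)
      g_in <- glom[inn]
      skels[[id]] <- patchy_skeleton(id, meshes[g_in])
      annotate(id, "LN", "patchy", "inhibitory")
      add_ln_synapses(id, g_in, spec$syn_per_glomerulus,
                      stats::setNames(spec$r, glom), character(0))
      add_marker_contact(id)
    })
  }

  # background LNs: each decoy class fails exactly one filter stage.
  # A: patchy morphology-matched but Untraced; B: patchy, no marker input;
  # C: patchy with marker input but dissimilar morphology; D: other subtypes.
  n_bg <- spec$n_other_lns
  n_a <- min(n_bg, ceiling(0.1 * n_bg))
  n_b <- min(n_bg - n_a, ceiling(0.1 * n_bg))
  n_c <- min(n_bg - n_a - n_b, ceiling(0.1 * n_bg))
  n_d <- n_bg - n_a - n_b - n_c
  decoy_type <- rep(c("A", "B", "C", "D"), times = c(n_a, n_b, n_c, n_d))
  other_subtypes <- c("ventral", "panglomerular", "oligoglomerular", "continuous")
  bg_ids <- sprintf("bLN_%03d", seq_len(n_bg))
  for (i in seq_along(bg_ids)) {
    id <- bg_ids[i]
    ty <- decoy_type[i]
    with_seed(substream_seed(spec$seed, id), {
      inn <- stats::rbinom(spec$n_glomeruli, 1L, spec$p) == 1L
      if (!any(inn)) inn[sample(spec$n_glomeruli, 1L)] <- TRUE
      g_in <- glom[inn]
      if (ty %in% c("A", "B")) {
        # morphology indistinguishable from a planted arbor
        donor <- patchy_ids[(i - 1L) %% length(patchy_ids) + 1L]
        skels[[id]] <- jitter_skeleton(skels[[donor]], id, sd = 100)
        g_in <- glom[innervation[donor, ] == 1L]
      } else if (ty == "C") {
        skels[[id]] <- patchy_skeleton(id, meshes[g_in],
                                       offset = c(0, 0, 1.2e5))
      } else {
        skels[[id]] <- patchy_skeleton(id, meshes[g_in])
      }
      subtype <- if (ty == "D") {
        other_subtypes[(i - 1L) %% length(other_subtypes) + 1L]
      } else "patchy"
      status <- if (ty == "A") "Untraced" else "Traced"
      annotate(id, "LN", subtype, "inhibitory", status = status)
      add_ln_synapses(id, g_in, 8L, stats::setNames(rep(0, spec$n_glomeruli), glom),
                      character(0))
      if (ty %in% c("A", "C")) add_marker_contact(id)
    })
  }

  # reference morphology library: jittered images of the planted arbors
  refs <- with_seed(substream_seed(spec$seed, "references"), {
    lapply(seq_along(patchy_ids), function(i) {
      jitter_skeleton(skels[[patchy_ids[i]]], sprintf("ref_%02d", i), sd = 100)
    })
  })

  conn <- connectome(
    skeletons = skels,
    connections = do.call(rbind, rows),
    annotations = do.call(rbind, ann),
    meshes = meshes
  )
  list(
    connectome = conn,
    ground_truth = list(
      patchy = patchy_ids,
      counts = do.call(rbind, gt_counts),
      polarity = do.call(rbind, gt_polarity),
      innervation = innervation,
      marker = "CSD"
    ),
    references = refs
  )
}

ann_lookup_class <- function(ann_df, ids) {
  ann_df$transmitter_class[match(ids, ann_df$neuron_id)]
}
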