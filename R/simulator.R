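# Synthetic vascular-tree cohort generator.
#
# Stands in for a private clinical fundus-photograph collection: each
# synthetic eye is a branching vascular tree obeying Murray's law at every
# bifurcation, rendered as dark anti-aliased vessels on a bright textured
# disc with a smooth illumination gradient, together with its exact binary
# vessel mask and bifurcation annotations. A class-conditional shift in
# bifurcation geometry (asymmetry ratio and opening angle) plants the
# "hypertension" signal; a diffuse caliber-shift mode provides the negative
# control for attribution analyses.

#' Create a simulator configuration
#'
#' Defaults define the package's reference synthetic world: 128-px images,
#' trees of up to 4 bifurcation generations from an 8-px root, Murray
#' exponent 3 (classical minimum-work value), normotensive asymmetry ratio
#' 0.75 +/- 0.10 and opening angle 75 +/- 12 degrees, with the
#' hypertension class shifted by `classEffect = -0.25` (more asymmetric
#' daughter widths). The angle shift defaults to 0: quantitative retinal
#' studies associate blood pressure with arteriolar branching asymmetry
#' ratios but not with branching angle, and a width-ratio effect is
#' intrinsically local to the junction, whereas an angle shift changes the
#' global spread of the whole subtree. The root diameter and depth are
#' sized so that daughter vessels stay above the 1-px recursion cutoff in
#' both classes: the class effect then lives in bifurcation geometry
#' alone rather than leaking into global branch density through
#' differential branch extinction. See [SimulatorConfig-class] for the
#' meaning of every knob.
#'
#' @param imageSize square image side in pixels (>= 64).
#' @param treeDepth maximum bifurcation generations.
#' @param rootDiameter root vessel diameter, pixels.
#' @param murrayExponent exponent m of \eqn{d_p^m = d_1^m + d_2^m}.
#' @param angleMean,angleSd opening-angle distribution, degrees.
#' @param asymmetryMean,asymmetrySd asymmetry-ratio distribution, in (0,1].
#' @param classEffect additive shift of `asymmetryMean` for the
#'   hypertension class (0 disables the class signal).
#' @param classEffectAngle additive shift of `angleMean`, degrees.
#' @param effectMode `"bifurcation"` (default) or `"diffuse"`.
#' @param caliberShift relative diameter shift in diffuse mode.
#' @param backgroundTextureSd,illuminationGradient,vesselContrast rendering
#'   knobs, dimensionless.
#' @param darkVessels vessel polarity flag.
#' @param twoEyeProb probability a subject contributes two images.
#' @param seed base seed.
#' @return a validated [SimulatorConfig-class].
#' @examples
#' cfg <- simulatorConfig(treeDepth = 3L)
#' tree <- sampleTree(cfg, seed = 1)
#' @export
simulatorConfig <- function(imageSize = 128L, treeDepth = 4L,
                            rootDiameter = 8, murrayExponent = 3,
                            angleMean = 75, angleSd = 12,
                            asymmetryMean = 0.75, asymmetrySd = 0.1,
                            classEffect = -0.25, classEffectAngle = 0,
                            effectMode = c("bifurcation", "diffuse"),
                            caliberShift = -0.18,
                            backgroundTextureSd = 0.04,
                            illuminationGradient = 0.25,
                            vesselContrast = 0.55, darkVessels = TRUE,
                            twoEyeProb = 0.4, seed = 1L) {
  effectMode <- match.arg(effectMode)
  tryCatch(
    new("SimulatorConfig", imageSize = as.integer(imageSize),
        treeDepth = as.integer(treeDepth), rootDiameter = rootDiameter,
        murrayExponent = murrayExponent, angleMean = angleMean,
        angleSd = angleSd, asymmetryMean = asymmetryMean,
        asymmetrySd = asymmetrySd, classEffect = classEffect,
        classEffectAngle = classEffectAngle, effectMode = effectMode,
        caliberShift = caliberShift,
        backgroundTextureSd = backgroundTextureSd,
        illuminationGradient = illuminationGradient,
        vesselContrast = vesselContrast, darkVessels = darkVessels,
        twoEyeProb = twoEyeProb, seed = as.integer(seed)),
    error = function(e) stopConfig(conditionMessage(e)))
}

# Daughter diameters from the parent diameter and a sampled asymmetry ratio
# alpha = (d2/d1)^2 (d2 <= d1), solving Murray's relation exactly:
# d1 = dp / (1 + alpha^(m/2))^(1/m), d2 = d1 * sqrt(alpha).
murrayDaughters <- function(dp, alpha, m) {
  d1 <- dp / (1 + alpha^(m / 2))^(1 / m)
  c(d1, d1 * sqrt(alpha))
}

#' Sample a synthetic vascular tree
#'
#' Grows a binary tree from a root at the temporal edge of the fundus disc.
#' At each bifurcation the asymmetry ratio and total opening angle are
#' drawn from the (class-shifted) configuration distributions, daughter
#' diameters at the junction solve Murray's relation exactly, and the
#' larger daughter deviates less from the parent direction. Each daughter
#' then tapers linearly to a width drawn from the class-independent
#' asymmetry distribution, which is what its subtree inherits: the class
#' effect is thereby confined to junction-proximal geometry and no global
#' caliber statistic separates the classes. Growth stops at `treeDepth`
#' generations, when a carried daughter width would fall below 1 pixel, or
#' when a branch would leave the fundus disc.
#'
#' @param config a [SimulatorConfig-class].
#' @param label class of the eye; the hypertension class receives the
#'   configured effect shifts.
#' @param seed integer seed making the tree reproducible.
#' @return a [VascularTree-class].
#' @export
sampleTree <- function(config, label = "non-hypertension", seed = 1L) {
  stopifnot(is(config, "SimulatorConfig"))
  validObject(config)
  if (!label %in% .CLASS_LEVELS)
    stopConfig("unknown label: ", label)
  hyper <- label == "hypertension"
  bifEffect <- hyper && config@effectMode == "bifurcation"
  aMean <- config@asymmetryMean + if (bifEffect) config@classEffect else 0
  thMean <- config@angleMean + if (bifEffect) config@classEffectAngle else 0
  calScale <- if (hyper && config@effectMode == "diffuse")
    1 + config@caliberShift else 1
  S <- config@imageSize
  ctr <- (S - 1) / 2
  R <- 0.48 * S
  m <- config@murrayExponent
  lenScale <- 3.2

  withSeed(seed, {
    rootDiam <- config@rootDiameter * calScale
    nodes <- matrix(c(ctr + 0.92 * R, ctr), 1, 2,
                    dimnames = list(NULL, c("x", "y")))
    segs <- data.frame(parent = integer(), child = integer(),
                       diameter = numeric(), diameterEnd = numeric())
    bifs <- data.frame(node = integer(), x = numeric(), y = numeric(),
                       d_parent = numeric(), d1 = numeric(), d2 = numeric(),
                       angle_deg = numeric(), asymmetry = numeric())
    # grow one branch segment; returns the new node index or NA if the
    # branch would leave the disc or be degenerate. When diamEnd differs
    # from diam, the width relaxes to diamEnd over a short junction-
    # proximal stub (about 1.5 parent diameters) via an intermediate node,
    # so the planted width signal stays confined to the junction
    # neighbourhood instead of being spread along the whole segment.
    growSeg <- function(from, dir, diam, diamEnd = diam) {
      len <- max(2, lenScale * max(diam, diamEnd)) * runif(1, 0.85, 1.15)
      p0 <- nodes[from, ]
      p1 <- p0 + len * c(cos(dir), sin(dir))
      # confine to the fundus disc: shrink toward the boundary if needed
      rr <- sqrt(sum((p1 - ctr)^2))
      if (rr > R - 1.5) {
        lo <- 0; hi <- 1
        for (it in 1:20) {
          mid <- (lo + hi) / 2
          if (sqrt(sum((p0 + mid * (p1 - p0) - ctr)^2)) > R - 1.5) hi <- mid
          else lo <- mid
        }
        p1 <- p0 + lo * (p1 - p0)
        if (sqrt(sum((p1 - p0)^2)) < 2) return(NA_integer_)
      }
      len <- sqrt(sum((p1 - p0)^2))
      if (diamEnd != diam && len > 4) {
        fTaper <- min(0.5, 1.5 * diam / len)
        pm <- p0 + fTaper * (p1 - p0)
        nodes <<- rbind(nodes, pm)
        mid <- nrow(nodes)
        segs <<- rbind(segs,
                       data.frame(parent = from, child = mid,
                                  diameter = diam, diameterEnd = diamEnd))
        from <- mid
        p0 <- pm
        diam <- diamEnd
      }
      nodes <<- rbind(nodes, p1)
      segs <<- rbind(segs, data.frame(parent = from,
                                      child = nrow(nodes),
                                      diameter = diam,
                                      diameterEnd = diamEnd))
      nrow(nodes)
    }
    truncNorm <- function(mu) min(1, max(0.05, rnorm(1, mu, config@asymmetrySd)))
    # queue of open branch tips: node index, direction, diameter, depth
    tip0 <- growSeg(1L, pi, rootDiam)
    queue <- if (is.na(tip0)) list() else
      list(list(node = tip0, dir = pi + rnorm(1, 0, 0.1), diam = rootDiam,
                depth = 0L))
    while (length(queue)) {
      tip <- queue[[1]]; queue <- queue[-1]
      if (tip$depth >= config@treeDepth) next
      # the class effect is planted in junction-proximal widths only:
      # alphaLocal (class-shifted) fixes the daughter widths AT the
      # bifurcation; each daughter tapers to a width drawn from the
      # class-independent distribution (alphaCarry), which is what its own
      # subtree inherits. No global width statistic then carries class
      # information -- the signal lives where both daughters are visible.
      alphaLocal <- truncNorm(aMean)
      alphaCarry <- truncNorm(config@asymmetryMean)
      theta <- min(170, max(10, rnorm(1, thMean, config@angleSd))) * pi / 180
      dd <- murrayDaughters(tip$diam, alphaLocal, m)
      ddCarry <- murrayDaughters(tip$diam, alphaCarry, m)
      if (ddCarry[2] < 1) next
      # the larger daughter deviates less from the parent direction
      w1 <- dd[2]^2 / sum(dd^2)
      side <- sample(c(-1, 1), 1)
      dirs <- tip$dir + side * c(w1 * theta, -(1 - w1) * theta) +
        rnorm(1, 0, 0.06)
      kids <- c(growSeg(tip$node, dirs[1], dd[1], ddCarry[1]),
                growSeg(tip$node, dirs[2], dd[2], ddCarry[2]))
      ok <- !is.na(kids)
      if (all(ok)) {
        bifs <- rbind(bifs, data.frame(
          node = tip$node, x = nodes[tip$node, 1], y = nodes[tip$node, 2],
          d_parent = tip$diam, d1 = dd[1], d2 = dd[2],
          angle_deg = theta * 180 / pi, asymmetry = alphaLocal))
      } else if (any(ok)) {
        # a clipped sibling leaves a continuation, not a bifurcation:
        # carry the parent diameter so Murray's relation is not violated
        # by a phantom branch (covers both the stub and the remainder)
        keep <- which(ok)
        node <- kids[keep]
        while (node != tip$node) {
          i2 <- which(segs$child == node)
          segs$diameter[i2] <- tip$diam
          segs$diameterEnd[i2] <- tip$diam
          node <- segs$parent[i2]
        }
        ddCarry[keep] <- tip$diam
      }
      for (i in which(ok))
        queue[[length(queue) + 1L]] <- list(node = kids[i], dir = dirs[i],
                                            diam = ddCarry[i],
                                            depth = tip$depth + 1L)
    }
    new("VascularTree", nodes = nodes, segments = segs,
        bifurcations = bifs, imageSize = S)
  })
}

#' Render a vascular tree to a fundus-style image and its vessel mask
#'
#' Vessels are drawn as anti-aliased curves of width equal to the segment
#' diameter, darkened by `vesselContrast` against a bright textured disc
#' with a smooth illumination gradient; everything outside the circular
#' field of view is black. The mask is the exact rasterization of the
#' segments at their widths (pixel centers within diameter/2 of a
#' centerline), bit-reproducible from the seed.
#'
#' @param tree a [VascularTree-class].
#' @param config the [SimulatorConfig-class] used to build the tree.
#' @param label class label carried onto the image.
#' @param subjectId subject identifier carried onto the image.
#' @param seed integer seed for background texture.
#' @return list with `image` ([FundusImage-class], provenance `"raw"`) and
#'   `mask` ([VesselMask-class]).
#' @export
renderTree <- function(tree, config, label = "non-hypertension",
                       subjectId = "s1", seed = 1L) {
  stopifnot(is(tree, "VascularTree"))
  S <- config@imageSize
  ctr <- (S - 1) / 2
  R <- 0.48 * S
  segs <- tree@segments
  segMat <- if (nrow(segs)) cbind(
    tree@nodes[segs$parent, 1], tree@nodes[segs$parent, 2],
    tree@nodes[segs$child, 1], tree@nodes[segs$child, 2],
    segs$diameter,
    if (is.null(segs$diameterEnd)) segs$diameter else segs$diameterEnd)
  else matrix(numeric(), 0, 6)
  r <- .render_segments_cpp(segMat, S)
  withSeed(seed, {
    xs <- matrix(rep(0:(S - 1), each = S), S, S)  # column index = x
    ys <- matrix(rep(0:(S - 1), S), S, S)         # row index = y
    phi <- runif(1, 0, 2 * pi)
    u <- ((xs - ctr) * cos(phi) + (ys - ctr) * sin(phi)) / S + 0.5
    bg <- 0.82 + config@illuminationGradient * (u - 0.5)
    if (config@backgroundTextureSd > 0) {
      noise <- matrix(rnorm(S * S), S, S)
      noise <- matrix(EBImage::imageData(
        EBImage::gblur(EBImage::Image(noise), sigma = 1.5)), S, S)
      noise <- noise / sd(noise) * config@backgroundTextureSd
      bg <- bg + noise
    }
    img <- if (config@darkVessels) bg - config@vesselContrast * r$coverage
    else (1 - bg) + config@vesselContrast * r$coverage
    disc <- ((xs - ctr)^2 + (ys - ctr)^2) <= R^2
    img[!disc] <- 0
    img <- clip01(img)
    list(image = new("FundusImage", pixels = img, label = label,
                     subjectId = subjectId, provenance = "raw"),
         mask = new("VesselMask", pixels = r$mask))
  })
}

#' Generate a labeled synthetic cohort
#'
#' Draws `nPerClass` eyes per class. Subjects contribute two eyes with
#' probability `twoEyeProb` (both eyes share the subject id and label, with
#' independently sampled trees), exercising subject-grouped fold splitting
#' downstream. Fully reproducible from `seed`.
#'
#' @param config a [SimulatorConfig-class].
#' @param nPerClass images per class (>= 1).
#' @param seed integer seed.
#' @return a list of class `"retinavascCohort"` with elements `records`
#'   (per image: `image`, `mask`, `tree`, `bifurcations`, `id`,
#'   `subjectId`, `label`) and `manifest` (data.frame with `id`,
#'   `subject_id`, `label`).
#' @export
generateCohort <- function(config, nPerClass, seed = config@seed) {
  if (nPerClass < 1) stopConfig("nPerClass must be >= 1")
  validObject(config)
  records <- list()
  withSeed(deriveSeed(seed, "cohort"), {
    subj <- 0L
    for (cls in .CLASS_LEVELS) {
      made <- 0L
      while (made < nPerClass) {
        subj <- subj + 1L
        sid <- sprintf("subj%04d", subj)
        nEyes <- if (runif(1) < config@twoEyeProb) 2L else 1L
        nEyes <- min(nEyes, nPerClass - made)
        for (eye in seq_len(nEyes)) {
          s <- sample.int(900000000L, 2L)
          tree <- sampleTree(config, label = cls, seed = s[1])
          rend <- renderTree(tree, config, label = cls, subjectId = sid,
                             seed = s[2])
          made <- made + 1L
          records[[length(records) + 1L]] <- list(
            id = sprintf("%s_%03d", substr(cls, 1, 3), made),
            subjectId = sid, label = cls, image = rend$image,
            mask = rend$mask, tree = tree,
            bifurcations = tree@bifurcations)
        }
      }
    }
  })
  manifest <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    subject_id = vapply(records, `[[`, "", "subjectId"),
    label = vapply(records, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  structure(list(records = records, manifest = manifest, config = config),
            class = "retinavascCohort")
}

#' @export
print.retinavascCohort <- function(x, ...) {
  cat(sprintf("retinavasc cohort: %d images (%s)\n", nrow(x$manifest),
              paste(sprintf("%s n=%d", names(table(x$manifest$label)),
                            table(x$manifest$label)), collapse = ", ")))
  invisible(x)
}
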