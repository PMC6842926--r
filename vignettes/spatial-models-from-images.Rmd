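---
title: "From segmented microscopy masks to spatial SBML models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From segmented microscopy masks to spatial SBML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgsbml)
```

## The problem

Spatial (reaction–diffusion) simulations of cell biology need a geometry:
which voxel is extracellular space, which is cytosol, which is nucleus,
and where the membranes between them lie. Microscopy provides this shape,
but as per-channel segmented binary images, not as a model. `imgsbml`
closes that gap: it converts one binary mask per cellular component into
an SBML Level 3 Version 1 document with the Spatial Processes package, in
which the geometry is a sampled field (a voxel array), every component is
a domainType with a distinct 8-bit sampled value, every contiguous region
is a domain, and membranes between adjacent domains are derived
automatically instead of being enumerated by hand — a chore that grows
quadratically with the number of labeled organelles if done manually, but
is linear in the number of real interfaces when derived from the
containment hierarchy.

Segmentation itself is out of scope: the package assumes upstream tools
have already produced one binary mask per component, and it deliberately
performs no smoothing, opening/closing with tunable kernels, or
resampling other than nearest neighbour.

## Pipeline and conventions

`convert_images()` runs the stages below; each is exported separately.

**Representation.** An `ImageStack` is a 3D integer array indexed
`(x, y, z)` (a 2D image has z-extent 1; TIFF pages are z-slices) with a
physical voxel spacing `(dx, dy, dz)` in arbitrary but consistent units.
Binary masks use foreground = 255, background = 0; `ensure_binary()` maps
any nonzero value to 255 and never touches the zero set. Voxel `(i,j,k)`
(0-based) sits at physical position `((i+0.5)dx, (j+0.5)dy, (k+0.5)dz)` —
the voxel-centre convention that places interior points unambiguously.

**Hole and gap filling.** Both are formulated as background flood fill
from the image border with 6-connectivity (the complement of the
26-connected foreground, which avoids the classic connectivity paradox of
using the same neighbourhood for both phases): background not reachable
from the border is enclosed, and enclosed background is foreground that
segmentation missed. `fill_holes()` applies this to a single mask;
`fill_gap()` applies it to the overlay of an inner and an outer mask and
assigns the enclosed gap to the **outer** region, preserving the inner
organelle's segmented boundary (the choice is a convention; the gap must
go somewhere, and the outer region is the one whose inner boundary was
unreliable in the first place). For single-slice images the degenerate z
axis contributes no border, so 2D holes behave as in 2D. No structuring
elements or iteration counts are involved — the flood-fill formulation
reproduces the intended effect without kernel parameters to tune.

**Z-interpolation.** Confocal stacks are typically undersampled along z.
`interpolate_z()` uses nearest-neighbour replication at the integer
factor `k = round(dz/dx)`: output slice `j` copies the input slice
nearest to `(j+0.5)/k − 0.5`, and `dz` becomes `dz/k`. Integer `k` keeps
the operation exactly invertible slice-wise (each output slice is a
verbatim copy, foreground counts scale by exactly `k`, and no new values
appear — important for already-labeled grids). `dx ≠ dy` is rejected:
in-plane anisotropy is not a microscopy artifact this tool should paper
over.

**Containment and overlap.** The hierarchy is derived from the masks
themselves: each mask's *filled* region (itself plus everything it
encloses) is compared by strict set inclusion, which makes the result
independent of whether masks arrive solid or already carved into shells.
The extracellular complement EC sits at depth 0 and needs no mask of its
own — a two-mask cytosol/nucleus input yields the expected three-volume
model. Masks that overlap partially with neither containing the other are
an error naming both masks, because no nesting order is defensible there.
Overlapping voxels are kept by the innermost claimant
(`resolve_overlap()`), so the nucleus keeps its voxels and the cytosol
becomes a shell; equal-depth siblings are ordered by descending voxel
count purely so that identifiers are deterministic.

**Sampled values.** With `N` volume domainTypes including EC, the type at
position `d` of the depth order receives `d·⌊255/N⌋`: 0/85/170 for the
three-volume model, 0/127 for a single mask. Using the position in the
depth-ordered list (rather than the raw depth) keeps values pairwise
distinct when siblings share a depth, which the distinctness invariant of
sampled fields requires; deeper regions always carry strictly larger
values.

**Domains and interior points.** Contiguous regions are labeled with
26-connectivity (8-connectivity in 2D), the particle-analysis convention
of the imaging ecosystem this tool lives in; the connectivity is an
argument of `label_domains()`. Ordinals within a domainType go to larger
regions first, ties broken by the lexicographically smallest minimum
voxel coordinate. The interior point of a domain maximizes the city-block
distance to any differently-valued voxel (computed by multi-source BFS,
which on an unobstructed grid *is* the city-block distance transform),
ties again broken lexicographically — deterministic, and guaranteed to
lie on the domain's own sampled value.

**Adjacency and membranes.** Two domains are adjacent iff they share a
voxel *face* (6-neighbourhood). Domains themselves use 26-connectivity,
but a zero-thickness membrane needs a shared face to have any area —
diagonal contact has none, so it creates no membrane. Each adjacency
between volume domains yields one membrane domain under a membrane
domainType named per ordered type pair: the canonical biological names
`PM` (Cyt|EC) and `NM` (Nuc|Cyt) where they apply, systematically
`<inner>_<outer>_membrane` otherwise. When two nuclei touch the same
cytosol, each contact gets its own membrane domain (`NM0`, `NM1`) under
the one shared `NM` type. Membranes carry no sampled value and no voxels;
they exist purely through their two ordered `adjacentDomains` records
(membrane↔inner, membrane↔outer). Adjacencies whose domainTypes differ by
anything other than one containment level — nucleus touching EC being the
canonical impossibility — produce *warnings*, not errors: the tool
reports suspect biology but does not refuse to export it.

**SBML encoding.** One compartment per domainType (volumes dimension 3,
membranes dimension 2), linked by a `compartmentMapping`. Compartment
SIds equal the domainType name and the domainType SId carries a
`_domainType` suffix, since SBML identifiers share one namespace and
users address compartments far more often. Volume compartment sizes are
`voxel_count · dx·dy·dz`, making the document simulation-ready. The voxel
array is serialized uncompressed, x fastest, then y, then z, as
space-separated integers; only uncompressed fields are accepted on
import. Kinetic laws are arithmetic expressions (`+ − * / ^`, function
calls, identifiers, numbers) normalized through the R parser and
serialized to the SBML MathML subset, so an export/import round trip
reproduces them exactly. Identifiers are sanitized to the SBML SId
grammar (non-alphanumerics to `_`). Import rejects documents that are not
Level 3 Version 1 or lack the spatial package.

**Validation.** All checks run offline and return issues as data
(severity, rule, offending id, message), never exceptions: core checks
(unique SIds, resolvable references, parseable math) and spatial checks
(distinct sampled values, every grid value mapped, one compartment per
domainType, membranes with exactly two adjacency records, interior points
on the right value, positive spacing), plus the biological-consistency
warnings. `export_sbml()` refuses on error-severity issues unless forced;
warnings never block.

## Synthetic data: what it covers and what it does not

The fixture generators produce the study conditions for all tests:
concentric spheres (`nested_spheres`, 32³ voxels, radii 12 and 6 by
default), the same with an enclosed background gap of configurable width
(`gapped_spheres`), several disjoint nuclei in one cytosol
(`multi_nucleus`), and z-decimated stacks (`anisotropic_stack`) that
`interpolate_z()` must restore. Spheres are used deliberately:
containment, adjacency, component counts and interior points are all
analytically checkable, and the generators are fully deterministic.

What passing on these fixtures shows: the labeling, adjacency, membrane
and serialization machinery is correct on geometries whose ground truth
is known exactly (cross-checked against igraph-components and all-pairs
brute-force oracles on ~10³ random small grids besides). What it does not
show: robustness to the irregular, noisy, possibly topologically messy
shapes of real segmentations — touching organelles, slivers one voxel
thick, segmentation speckle. The preprocessing stages address the common
artifacts (holes, gaps, anisotropy) but perform no denoising, and a
speckled mask will faithfully produce one domain per speckle.

## Numerical and scale choices

Grids in the tests and the acceptance script are 16³–32³ voxels — large
enough that spheres have genuine interiors, shells and curvature, small
enough that exhaustive oracles remain exact companions. Oracle
equivalence runs 1,000 random grids of up to 6×6×6 voxels under a fixed
seed. The BFS primitives are vectorised layer-by-layer frontier
expansions, linear in voxels per component; the merged grid for a
two-component model occupies one integer per voxel. Degenerate inputs are
defined, not special-cased: an empty mask list yields the EC-only model
(one domainType, one domain, no adjacency), a radius-0 sphere an empty
mask, identical masks an emptied outer region with a warning.

## Known limitations

- TIFF resolution metadata is read (resolution tags, ImageJ-style
  `spacing=`) but not written: the R TIFF writer used does not emit these
  tags, so spacing must be passed explicitly when re-reading exported
  grayscale images (`--spacing`, or the `spacing` argument).
- Sampled-field geometry only; no CSG/parametric/mesh geometries, no
  compressed sampled fields on import, no SBML Level 2, no simulation.
- The sampled-value formula generalizes the printed three-type instance;
  other tools may assign different values to additional organelles, so
  numeric values should be compared via the domainType mapping, not
  assumed.
- Membrane surface area is not computed; the per-edge shared-face counts
  are kept internally as a contact-area proxy but not serialized.
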