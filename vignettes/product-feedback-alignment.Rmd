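---
title: "Product feedback alignment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Product feedback alignment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfanet)
```

## The problem and the model

Backpropagation computes the error at layer $l$ of a multilayer network
$x_{l+1} = \sigma(W_{l+1,l} x_l + b_{l+1})$ by the recursion
$e_l = \sigma'(x_l) \odot (W_{l+1,l}^\top e_{l+1})$, starting from the output
teaching signal $e_L = -\partial \mathcal{L}/\partial x_L$ (softmax
cross-entropy here), and updates
$\Delta W_{l+1,l} = \eta\, e_{l+1} x_l^\top$. The backward pathway reuses the
transpose of every forward weight — a synapse-level copying ("weight
transport") that biological circuits cannot perform.

Product feedback alignment (PFA) replaces $W^\top$ by a factored pathway
through an expanded intermediate population of
$\bar N_l = (1/\lambda)\, N_{l+1}$ neurons:

$$\bar e_l = B_{l,l+1} e_{l+1}, \qquad
  e_l = \sigma'(x_l) \odot (R_{l,l}\, \bar e_l),$$

with $B$ fixed and random (entries i.i.d. mean 0, variance $1/\bar N_l$) and
$R$ plastic, updated by the purely local rule
$\Delta R_{l,l} = \eta\, x_l \bar e_l^\top$, with multiplicative weight decay
on both $W$ and $R$. The alignment mechanism is a random-matrix fact: for
the product pathway,
$\Delta (R B)^\top = \eta\, B^\top B\, e_{l+1} x_l^\top$, and $B^\top B$
concentrates at the identity as the expansion ratio $1/\lambda$ grows — its
eigenvalue density follows the Marchenko–Pastur law with support
$[(1\pm\sqrt\lambda)^2]$. So $W$ and $(RB)^\top$ receive (nearly) identical
update streams, and once weight decay has erased the initializations the two
agree up to the $O(\sqrt\lambda)$ fluctuation of $B^\top B$. At
$1/\lambda = 10$ the residual path-alignment angle is
$\arccos(1/\sqrt{1+\lambda}) \approx 17.5^\circ$.

Two limits tie the family together and are enforced by exact tests:
with $B = I$ ($\bar N = N_{l+1}$) PFA *is* the Kolen–Pollack rule; with
$\eta_R = 0$ and no $R$ decay it *is* feedback alignment with fixed feedback
$R_0 B_0$. With semi-orthogonal $B$ ($B^\top B = I$, the `pfa_o` variant) and
matched initialization $R_0 = W_0^\top B^\top$, the identity $R B = W^\top$
holds after every SGD step and PFA-o reproduces BP's trajectory to machine
precision.

## Conventions that must be fixed for exactness

* **Sign of the error.** $e = -\partial\mathcal{L}/\partial x$ everywhere,
  so all updates are additive ($W \leftarrow (1-\gamma)W + \eta\,
  \overline{e x^\top}$). The error stack is carried in preactivation
  coordinates: the recursion applies $\sigma'$ of the *receiving* layer at
  its cached preactivation, which is the quantity the weight update needs.
* **Batching.** Errors are per-sample; updates average (not sum) over the
  minibatch, keeping $\eta$ comparable across batch sizes.
* **ReLU at 0.** $\sigma'(0) = 0$ (subgradient choice); any fixed choice
  works, but it must be fixed for the exact-reduction tests to hold bitwise.
* **Decay.** Applied multiplicatively per minibatch step (decoupled-decay
  style), in a two-phase schedule: a large `wd_initial` for the first
  `wd_switch_epoch` epochs — whose role is to erase $W_0$ and $R_0$, the
  only sources of misalignment — then a small `wd_main`. Biases get no
  decay and have no feedback analogue.
* **Optimizer.** Plain SGD; the update rules above are plain gradient steps,
  and momentum/adaptive optimizers are deliberately out of scope.

## Convolutional layers

Feature maps are `(height, width, channel, batch)` arrays and kernels
`(kh, kw, in, out)`. The forward pass, the input-gradient (transposed
convolution) and the kernel gradient are all expressed through one patch
matrix (im2col) and its adjoint, so the 180° kernel flip of the gradient
operator is implicit; explicit-loop oracles in the test suite validate the
equivalence. For PFA, `B` is a 1×1 channel-mixing matrix applied at the
layer-$(l+1)$ resolution — keeping $\bar e$ the same spatial size as
$e_{l+1}$, so the $R$ update is a standard kernel-gradient — and `R` carries
all of $W$'s spatial hyperparameters (stride, padding, dilation) through the
transposed-convolution operator. Grouped convolution is not supported
(`groups = 1` is validated); it is only needed by large residual
architectures outside this package's scope, as are batch norm and pooling.
The printed shape of the 1×1 conv `B` in the source literature has
$N_l$ as its last axis, but `B` multiplies $e_{l+1}$; the implementation
uses $N_{l+1}$.

## Diagnostics

* **Alignment angle**: $\angle(\mathrm{vec}\,W^\top, \mathrm{vec}\,M)$ in
  degrees, where $M$ is the backward object — $B$ for FA, $\mathrm{sign}
  (W^\top)c_l$ for SF, the product $RB$ (dense) or the contracted effective
  kernel (conv) for PFA. 0° means a BP-equivalent pathway. Zero-norm inputs
  raise an error rather than returning 0.
* **Norm ratio**: $\|M\|_F / \|W^\top\|_F$; values near 1 mean stable error
  magnitudes. The norm is Frobenius on the vectorized weights, the same
  vectorization the angle uses (the spectral norm would be the other
  defensible reading; Frobenius keeps the two diagnostics on one footing).
* Metrics are recorded at epoch end, not per step.
* SF's per-layer magnitude is $c_l = \mathrm{mean}|W|$ of the current
  forward weights, recomputed each backward pass — parameter-free and keeps
  the SF norm ratio near 1.
* DFA's feedback has no object comparable to $W^\top$ (it skips layers), so
  it appears in no alignment table.

## Synthetic tasks, and what passing them does not show

`gen_teacher_task()` draws standard-Gaussian inputs and labels them with the
argmax of a fixed random teacher network (linear for depth 1, tanh hidden
layers otherwise), with optional uniform label noise; `gen_conv_task()` does
the same with a small random conv teacher, rejecting images whose top-two
teacher logits differ by less than a margin (without the margin, images that
silence every ReLU feature get tied, arbitrary labels and cap any learner's
accuracy). Both are bit-reproducible from their seed. They emulate small,
balanced, learnable classification problems; they do not have the spatial
statistics, class structure or sample sizes of natural image data, so
passing regimes here demonstrate the *mechanisms* (alignment, reductions,
sparsity behavior) rather than dataset-level performance claims. The MNIST
IDX reader is provided for running the same protocols on real digits from
local files; nothing is downloaded.

## The two benchmark protocols

`alignment_benchmark()` is the desk-scale analogue of the classic
784–512–512–10 MNIST diagnostic: a 100–256–256–10 ReLU network on a
10-class depth-2 teacher task (3000 train / 1000 test), batch 64,
$\eta = 0.1$, 40 epochs, expansion ratio 10. PFA-family runs use the
two-phase decay ($10^{-2}$ for 5 epochs, then $10^{-4}$); FA and SF use the
constant small decay, because they have no plastic feedback whose
initialization must be erased — a large early decay would artificially align
FA's forward weights to its fixed feedback. Sizes were chosen so the full
four-algorithm benchmark runs in about two minutes on one CPU core while the
characteristic regimes are already stable: PFA's path angle settles at the
ratio-10 random-matrix floor (~18°), PFA-o heads toward 0°, FA's layer-mean
weight angle stays above 60°, SF sits near 30°, and PFA's path norm ratio
near 1. One scale effect is worth naming: the output-adjacent layer aligns
more strongly at this width than in wide-network runs (its 10-dimensional
error is low-rank relative to 256 hidden units), so the FA criterion is read
on the layer mean, which is the stable quantity across scales.

`sparsity_benchmark()` probes heavy feedback sparsity ($p = 0.9$ zeros fixed
at initialization in $B$, and in $R$ for PFA). The protocol is
capacity-tight (16–12–8) and convergence-length (200 epochs,
$\eta = 0.3$) by design: at $p = 0.9$ a sparse feedback row into a narrow
layer leaves a Poisson-sized fraction of FA's hidden units with no error
signal at all, while PFA's product $RB$ stays dense thanks to the expanded
intermediate population — at ratio 10 and 90% sparsity PFA retains as many
feedback synapses as dense FA. The sparse pathway attenuates PFA's error
signal by $\approx(1-p)$ versus $\approx\sqrt{1-p}$ for FA, so PFA needs
more steps to bootstrap; comparing before convergence measures that
transient, not the property. Under this protocol PFA's mean final accuracy
exceeds FA's by several points over 5 seeds.

## Numerical choices and degenerate inputs

* Semi-orthogonalization is QR of a Gaussian matrix with the sign of
  $\mathrm{diag}(R)$ fixed, giving a Haar-distributed column space; it
  requires $\bar N \ge N_{l+1}$ and errors otherwise.
* Eigenvalues of $B^\top B$ are clipped at 0 (the matrix is PSD; `eigen`
  round-off can produce $-10^{-16}$).
* Finite-size slack for spectrum-support checks is 0.1 at $N = 200$
  (edge fluctuations shrink like $N^{-2/3}$, so the slack should scale
  accordingly at other sizes).
* Softmax is max-shifted before exponentiation; log-probabilities are
  floored at $10^{-300}$.
* Non-finite losses or updates abort training with the epoch and batch
  named; a target outside `1..n_classes`, a shape mismatch (named by
  layer), reading an IDX file with a wrong magic number or truncated
  payload (byte offset reported) are all structured errors.
* All randomness in a harness run derives from one master seed through
  named substreams (init / feedback / data / mask), so adding an algorithm
  or metric never perturbs another run's draws, and `(config, data)`
  reproduces a run bit-for-bit.

## Known limitations

Dense and conv layers only (no batch norm, pooling, residual blocks, or
grouped convolution); plain SGD; `sf`, `dfa` and `kp` are dense-only
(`bp`, `fa`, `pfa`, `pfa_o` cover conv networks). The intermediate
population multiplies the memory and time cost of the backward pass by the
expansion ratio, which is the price of avoiding weight transport. Plastic
$B$ (learning the random projection itself) is out of scope. Convolutional
weight sharing across spatial positions is itself a biologically questioned
assumption that this package inherits.
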