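# usreg

Segmentation-based registration of 3D intraoperative ultrasound (iUS) for
image-guided neurosurgery.

During glioma resection the brain deforms (*brain shift*), so ultrasound
volumes acquired at successive surgical stages — before opening the dura,
during resection, after resection — must be registered before they can be
compared. Later-stage acquisitions are degraded by debris, blood and
resection-cavity artefacts, which makes direct intensity-based iUS–iUS
registration fragile. `usreg` instead registers the *structures that stay
visible*: hyperechogenic sulci and falx cerebri are segmented in each
volume by a 3D U-Net, and the binary masks drive a mono-modal variational
registration.

The registration minimizes

    J(φ) = SSD(R, T∘φ) + α·S(u),

with `SSD` the sum of squared differences between the reference mask `R`
and the deformed template mask, and `S` the linear-elastic potential of
the displacement `u` (Lamé parameters `μ`, `λ`), discretized on the voxel
grid and minimized by limited-memory BFGS (discretize-then-optimize).
A parametric pre-alignment (translation, then rigid, one pyramid level
coarser, starting from the tracker's guess) initializes a three-level
coarse-to-fine nonparametric elastic stage. Evaluation uses landmark
target registration error (TRE), Dice overlap (plain and
correspondence-restricted), and capture-range estimation under the
80%-success rule.

A synthetic phantom module generates US-like volumes — curved, patchy,
bright sheets over multiplicative speckle — with exact ground-truth
masks, landmark correspondences, known smooth deformations and simulated
resection cavities, so the whole pipeline is testable at desk scale
without clinical data.

## Worked example

Register a phantom against a deformed copy of itself using the
ground-truth masks, then evaluate the landmark error per stage:

```r
library(usreg)

case <- generate_phantom(phantom_spec(seed = 100 + 1))       # 64^3, 0.5 mm
f    <- random_smooth_field(case$volume, max_mm = 4, seed = 200 + 1)
def  <- deform_phantom(case, f)                 # exact landmark ground truth

rep <- run_pair(phantom_pair(def, case))        # segment-free: masks supplied
print(rep)
#> <pipeline_report>
#>   mean initial distance:       1.63 mm (sd 0.62, range 0.75-2.67, n=15)
#>   after parametric:            1.06 mm (sd 0.41, range 0.33-1.56, n=15)
#>   after nonparametric:         0.39 mm (sd 0.21, range 0.12-0.82, n=15)
#>   converged: FALSE
```

The three rows are the stage-wise mean landmark distances: the initial
misalignment (here a synthetic smooth deformation peaking at 4 mm), the
error left after the translation/rigid stage, and the error after the
elastic stage. `converged: FALSE` only records that the optimizer used
its full iteration budget rather than stopping on a tolerance; descent is
guaranteed either way.

Training and applying the segmenter on a phantom (a capacity check that
overfits a single case):

```r
cfg <- unet_config(patch_size = c(12, 12, 12), padding = c(2, 2, 2),
                   batch_size = 6, val_samples = 20, val_interval = 50,
                   max_iterations = 2000, early_stop_val_jaccard = 0.9,
                   seed = 7)
case  <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 5))
model <- train_unet(dataset_split(train = list(case), validation = list(case)), cfg)
pred  <- predict_mask(model, case$volume)
jaccard(pred$binary, case$mask)
#> [1] 0.8996247
```

A thin command-line front end is installed with the package
(`exec/usreg`): `usreg phantom`, `usreg register`, `usreg tre`,
`usreg dice` wrap the same functions for shell use.

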