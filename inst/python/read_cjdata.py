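"""Dump the image and label of a cjdata-style HDF5 .mat file.

Usage: python read_cjdata.py <file.mat> <out.csv>
Writes the raw image matrix as CSV to <out.csv> and prints the numeric
label (last line of stdout).
"""
import sys

import h5py
import numpy as np


def main(path, out_csv):
    with h5py.File(path, "r") as f:
        if "cjdata" not in f:
            sys.stderr.write("no cjdata group\n")
            return 3
        grp = f["cjdata"]
        if "label" not in grp or "image" not in grp:
            sys.stderr.write("cjdata missing image/label\n")
            return 3
        label = int(np.asarray(grp["label"]).ravel()[0])
        img = np.asarray(grp["image"], dtype=float)
    # MATLAB stores column-major; h5py yields the transposed view
    np.savetxt(out_csv, img.T, delimiter=",", fmt="%.17g")
    print(label)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1], sys.argv[2]))
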