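{
  "simulation": {
    "code": "NWChem",
    "version": "synthetic-log"
  },
  "calculations": [
    {
      "id": "Calculation.1",
      "calculationSetup": {
        "id": "Setup.1",
        "theory": "scf",
        "task": "energy",
        "basisSet": {
          "id": "BasisSet.1",
          "name": "sto-3g"
        }
      },
      "molecule": {
        "id": "Molecule.1",
        "atoms": [
          {
            "id": "Atom.1.Mol.1",
            "element": "O",
            "coordinates": {
              "value": [0, 0, 0],
              "units": "angstrom"
            }
          },
          {
            "id": "Atom.2.Mol.1",
            "element": "H",
            "coordinates": {
              "value": [0.757, 0.586, 0],
              "units": "angstrom"
            }
          },
          {
            "id": "Atom.3.Mol.1",
            "element": "H",
            "coordinates": {
              "value": [-0.757, 0.586, 0],
              "units": "angstrom"
            }
          }
        ]
      },
      "calculationResults": {
        "totalEnergy": {
          "value": -74.965901,
          "units": "hartree"
        }
      }
    },
    {
      "id": "Calculation.2",
      "calculationSetup": {
        "id": "Setup.2",
        "theory": "scf",
        "task": "frequency",
        "basisSet": "BasisSet.1"
      },
      "molecule": "Molecule.1",
      "calculationResults": {
        "totalEnergy": {
          "value": -74.965901,
          "units": "hartree"
        },
        "vibrationalFrequencies": {
          "value": [1595, 3657.05, 3755.93],
          "units": "cm-1"
        },
        "vibrationalIntensities": {
          "value": [65, 4, 50],
          "units": "km/mol"
        }
      }
    }
  ]
}
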