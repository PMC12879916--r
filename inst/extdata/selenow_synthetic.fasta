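>SELENOW_synthetic synthetic 85-residue selenoprotein W analogue (Sec at position 13); not a database sequence
MALAVGDEGSLKUCGADSTNPEYFQLRGGVTSAPDNKEVFDAATSLGHMWNRLIPTGSEK
VYADGSTFEPNQALKTSGVDELYGR
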