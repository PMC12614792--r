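id,name,anchor_low,anchor_high,question,cluster
1,colour vibrancy,dull,vibrant,"how richly coloured is the material, ranging from monochromatic or neutral-coloured materials to vibrantly coloured materials?",light_and_colour
2,surface roughness,smooth,rough,"how rough is the material, ranging from fine or smooth to coarse or grainy?",texture_and_pattern
3,pattern complexity,plain,complex,"how complex are the patterns on the material, ranging from simple to intricate?",texture_and_pattern
4,striped pattern,no stripes,pronounced stripes,to what extent does the material exhibit stripy patterns?,texture_and_pattern
5,chequered pattern,no checks,pronounced checks,to what extent does the material exhibit chequered patterns?,texture_and_pattern
6,brightness,dark,bright,"how bright is the material, ranging from dim or subdued to bright or luminous?",light_and_colour
7,shininess,matt,mirror,"how shiny is the material, ranging from dull or non-reflective to highly reflective?",gloss
8,sparkle,none,sparkling,to what extent does the material exhibit sparkling and glittery effects?,gloss
9,hardness,soft,hard,"how hard is the material, ranging from soft or plush to firm or rigid?",physical
10,movement effect,none,extreme,to what extent does the appearance change due to camera movement?,gloss
11,pattern scale,fine,large,"how large are the pattern elements, ranging from fine-grained or uniform to large or blotchy patterns?",texture_and_pattern
12,naturalness,manmade,natural,"how natural is the material, ranging from man-made to natural origin?",abstract
13,thickness,flat,thick,"how deep is the material structure, ranging from flat or thin to thick?",physical
14,multicoloured,single,many,"how multicoloured is the material, ranging from a single or uniform colour to colourful or many colours?",light_and_colour
15,value,cheap,luxurious,"how valuable is the material, ranging from low-cost or cheap to extravagant or luxurious?",abstract
16,warmth,cold,warm,"how warm is the material to the touch, ranging from cool or cold to pleasant or warm?",physical
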