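/* Minimal HDF5 bindings for the seq2cov dataset container.
 *
 * Only what the container needs: double datasets of rank <= 4 addressed by
 * slash-separated paths (intermediate groups auto-created), and scalar
 * string attributes on the file root. R arrays are column-major; dims are
 * reversed on write and on read, so external row-major readers see the same
 * logical axis order as R.
 */

#include <hdf5.h>
#include <string.h>
#include <stdlib.h>

#include <R.h>
#include <Rinternals.h>

#define MAX_RANK 4

static void s2c_silence_hdf5(void)
{
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

SEXP C_h5_write(SEXP path, SEXP names, SEXP arrays,
                SEXP attr_names, SEXP attr_values)
{
    s2c_silence_hdf5();
    const char *fpath = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fcreate(fpath, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0)
        error("cannot create HDF5 file '%s'", fpath);

    hid_t lcpl = H5Pcreate(H5P_LINK_CREATE);
    H5Pset_create_intermediate_group(lcpl, 1);

    int n = LENGTH(names);
    for (int i = 0; i < n; i++) {
        const char *dname = CHAR(STRING_ELT(names, i));
        SEXP arr = VECTOR_ELT(arrays, i);
        if (TYPEOF(arr) != REALSXP) {
            H5Pclose(lcpl); H5Fclose(file);
            error("dataset '%s': expected a double array", dname);
        }
        SEXP dim = Rf_getAttrib(arr, R_DimSymbol);
        int rank;
        hsize_t dims[MAX_RANK];
        if (dim == R_NilValue) {
            rank = 1;
            dims[0] = (hsize_t) XLENGTH(arr);
        } else {
            rank = LENGTH(dim);
            if (rank > MAX_RANK) {
                H5Pclose(lcpl); H5Fclose(file);
                error("dataset '%s': rank %d > %d unsupported",
                      dname, rank, MAX_RANK);
            }
            for (int j = 0; j < rank; j++)
                dims[j] = (hsize_t) INTEGER(dim)[rank - 1 - j];
        }
        hid_t space = H5Screate_simple(rank, dims, NULL);
        hid_t dset = H5Dcreate2(file, dname, H5T_NATIVE_DOUBLE, space,
                                lcpl, H5P_DEFAULT, H5P_DEFAULT);
        if (dset < 0) {
            H5Sclose(space); H5Pclose(lcpl); H5Fclose(file);
            error("cannot create dataset '%s' in '%s'", dname, fpath);
        }
        herr_t st = H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL,
                             H5P_DEFAULT, REAL(arr));
        H5Dclose(dset);
        H5Sclose(space);
        if (st < 0) {
            H5Pclose(lcpl); H5Fclose(file);
            error("failed writing dataset '%s' to '%s'", dname, fpath);
        }
    }
    H5Pclose(lcpl);

    int na = LENGTH(attr_names);
    if (na > 0) {
        hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
        for (int i = 0; i < na; i++) {
            const char *an = CHAR(STRING_ELT(attr_names, i));
            const char *av = CHAR(STRING_ELT(attr_values, i));
            hid_t atype = H5Tcopy(H5T_C_S1);
            H5Tset_size(atype, strlen(av) + 1);
            H5Tset_strpad(atype, H5T_STR_NULLTERM);
            hid_t aspace = H5Screate(H5S_SCALAR);
            hid_t attr = H5Acreate2(root, an, atype, aspace,
                                    H5P_DEFAULT, H5P_DEFAULT);
            if (attr < 0) {
                H5Sclose(aspace); H5Tclose(atype);
                H5Gclose(root); H5Fclose(file);
                error("cannot create attribute '%s' in '%s'", an, fpath);
            }
            H5Awrite(attr, atype, av);
            H5Aclose(attr);
            H5Sclose(aspace);
            H5Tclose(atype);
        }
        H5Gclose(root);
    }
    H5Fclose(file);
    return R_NilValue;
}

static hid_t s2c_open(const char *fpath)
{
    hid_t file = H5Fopen(fpath, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0)
        error("cannot open '%s' as HDF5 (missing, corrupted or not HDF5)",
              fpath);
    return file;
}

SEXP C_h5_read(SEXP path, SEXP name)
{
    s2c_silence_hdf5();
    const char *fpath = CHAR(STRING_ELT(path, 0));
    const char *dname = CHAR(STRING_ELT(name, 0));
    hid_t file = s2c_open(fpath);
    hid_t dset = H5Dopen2(file, dname, H5P_DEFAULT);
    if (dset < 0) {
        H5Fclose(file);
        error("no dataset '%s' in '%s'", dname, fpath);
    }
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank < 0 || rank > MAX_RANK) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        error("dataset '%s': unsupported rank", dname);
    }
    hsize_t dims[MAX_RANK];
    H5Sget_simple_extent_dims(space, dims, NULL);
    R_xlen_t total = 1;
    for (int j = 0; j < rank; j++)
        total *= (R_xlen_t) dims[j];
    SEXP out = PROTECT(allocVector(REALSXP, total));
    herr_t st = H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL,
                        H5P_DEFAULT, REAL(out));
    H5Sclose(space);
    H5Dclose(dset);
    H5Fclose(file);
    if (st < 0) {
        UNPROTECT(1);
        error("failed reading dataset '%s' from '%s'", dname, fpath);
    }
    if (rank > 1) {
        SEXP dim = PROTECT(allocVector(INTSXP, rank));
        for (int j = 0; j < rank; j++)
            INTEGER(dim)[j] = (int) dims[rank - 1 - j];
        Rf_setAttrib(out, R_DimSymbol, dim);
        UNPROTECT(1);
    }
    UNPROTECT(1);
    return out;
}

SEXP C_h5_exists(SEXP path, SEXP name)
{
    s2c_silence_hdf5();
    const char *fpath = CHAR(STRING_ELT(path, 0));
    const char *dname = CHAR(STRING_ELT(name, 0));
    hid_t file = s2c_open(fpath);

    /* H5Lexists needs every intermediate group checked in turn */
    char *buf = (char *) R_alloc(strlen(dname) + 1, 1);
    strcpy(buf, dname);
    int ok = 1;
    char partial[1024] = "";
    char *tok = strtok(buf, "/");
    while (tok != NULL && ok) {
        if (strlen(partial) + strlen(tok) + 2 > sizeof(partial)) {
            ok = 0;
            break;
        }
        strcat(partial, "/");
        strcat(partial, tok);
        if (H5Lexists(file, partial, H5P_DEFAULT) <= 0)
            ok = 0;
        tok = strtok(NULL, "/");
    }
    H5Fclose(file);
    return ScalarLogical(ok);
}

SEXP C_h5_read_attr(SEXP path, SEXP name)
{
    s2c_silence_hdf5();
    const char *fpath = CHAR(STRING_ELT(path, 0));
    const char *aname = CHAR(STRING_ELT(name, 0));
    hid_t file = s2c_open(fpath);
    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    if (H5Aexists(root, aname) <= 0) {
        H5Gclose(root); H5Fclose(file);
        error("no root attribute '%s' in '%s'", aname, fpath);
    }
    hid_t attr = H5Aopen(root, aname, H5P_DEFAULT);
    hid_t atype = H5Aget_type(attr);
    size_t sz = H5Tget_size(atype);
    char *buf = (char *) R_alloc(sz + 1, 1);
    memset(buf, 0, sz + 1);
    hid_t memtype = H5Tcopy(H5T_C_S1);
    H5Tset_size(memtype, sz + 1);
    herr_t st = H5Aread(attr, memtype, buf);
    H5Tclose(memtype);
    H5Tclose(atype);
    H5Aclose(attr);
    H5Gclose(root);
    H5Fclose(file);
    if (st < 0)
        error("failed reading attribute '%s' from '%s'", aname, fpath);
    return mkString(buf);
}
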